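#' Construct a FieldOfView
#'
#' @param pixels named list of numeric matrices, or a single matrix.
#' @param channelRoles named integer vector mapping roles to channels; when
#'   omitted, list names are used as roles in order.
#' @param pixelSizeUm micrometres per pixel.
#' @param fovSizeUm physical extent; defaults to `n_px * pixelSizeUm`.
#' @return a [FieldOfView-class].
#' @examples
#' fov <- FieldOfView(list(plaque = matrix(0, 64, 64)), pixelSizeUm = 0.43)
#' pixelSize(fov)
#' @export
FieldOfView <- function(pixels, channelRoles = NULL, pixelSizeUm, fovSizeUm = NULL) {
  if (is.matrix(pixels)) pixels <- list(channel1 = pixels)
  if (!is.numeric(pixelSizeUm) || length(pixelSizeUm) != 1L || pixelSizeUm <= 0)
    stop("pixelSizeUm must be a single positive number")
  if (is.null(channelRoles)) {
    nm <- names(pixels)
    if (is.null(nm)) nm <- paste0("channel", seq_along(pixels))
    channelRoles <- setNames(seq_along(pixels), nm)
  }
  if (is.null(fovSizeUm)) fovSizeUm <- nrow(pixels[[1]]) * pixelSizeUm
  new("FieldOfView",
    pixels = pixels,
    channelRoles = setNames(as.integer(channelRoles), names(channelRoles)),
    pixelSizeUm = pixelSizeUm, fovSizeUm = fovSizeUm
  )
}

emptyGroundTruth <- function(nx = 0L, ny = 0L) {
  new("GroundTruth",
    plaqueLabels = matrix(0L, nx, ny),
    plaqueTable = data.frame(
      plaque_id = integer(), cx_px = numeric(), cy_px = numeric(),
      radius_um = numeric(), core_fraction = numeric()
    ),
    microgliaLabels = matrix(0L, nx, ny),
    microgliaTable = data.frame(
      cell_id = integer(), soma_x_px = numeric(), soma_y_px = numeric(),
      soma_radius_um = numeric(), process_length_um = numeric(),
      plaque_associated = logical()
    ),
    branches = list(),
    spotPositions = matrix(numeric(), ncol = 2,
      dimnames = list(NULL, c("x", "y")))
  )
}

.groupDefaults <- list(
  # Group-wise defaults emulate the reported study structure: dose-response
  # slopes of A-beta-42 on APOE per genotype, high soluble-aggregate counts in
  # the knockout with essentially no fibrillar plaques, larger/less compact
  # plaques under APOE2/APOE4 than APOE3, and microglial recruitment scaling
  # with plaque area fraction.
  APOEKO = list(
    plaqueDensity = 0.2, plaqueDiameterMeanlog = log(18), plaqueDiameterSdlog = 0.30,
    coreFractionShape1 = 3, coreFractionShape2 = 3,
    apoeMeanlog = log(1), apoeSdlog = 0.30,
    abetaSlope = 0, abetaIntercept = 60, abetaNoiseSd = 15,
    microgliaBaseDensity = 35, paRecruitmentCoeff = 731.09,
    migrationCoeff = 4, spotRate = 150
  ),
  APOE2 = list(
    plaqueDensity = 10, plaqueDiameterMeanlog = log(30), plaqueDiameterSdlog = 0.45,
    coreFractionShape1 = 3, coreFractionShape2 = 3,
    apoeMeanlog = log(40), apoeSdlog = 0.45,
    abetaSlope = 0.11, abetaIntercept = 220, abetaNoiseSd = 2.4,
    microgliaBaseDensity = 35, paRecruitmentCoeff = 731.09,
    migrationCoeff = 4, spotRate = 80
  ),
  APOE3 = list(
    plaqueDensity = 7, plaqueDiameterMeanlog = log(25), plaqueDiameterSdlog = 0.35,
    coreFractionShape1 = 6, coreFractionShape2 = 2,
    apoeMeanlog = log(40), apoeSdlog = 0.45,
    abetaSlope = 0.005, abetaIntercept = 235, abetaNoiseSd = 2.2,
    microgliaBaseDensity = 35, paRecruitmentCoeff = 731.09,
    migrationCoeff = 4, spotRate = 40
  ),
  APOE4 = list(
    plaqueDensity = 14, plaqueDiameterMeanlog = log(32), plaqueDiameterSdlog = 0.45,
    coreFractionShape1 = 3, coreFractionShape2 = 3,
    apoeMeanlog = log(40), apoeSdlog = 0.45,
    abetaSlope = 0.23, abetaIntercept = 215, abetaNoiseSd = 3.4,
    microgliaBaseDensity = 35, paRecruitmentCoeff = 731.09,
    migrationCoeff = 4, spotRate = 40
  )
)

# reported microglial depletion under CSF1R inhibition: 83% / 77% / 87%
.plxDepletion <- c(APOE2 = 0.83, APOE3 = 0.77, APOE4 = 0.87)

# treatment shifts of mean guanidine-soluble A-beta-42 (APOE-adjusted betas)
.plxAbetaOffset <- c(APOE2 = -148.2, APOE3 = -28.53, APOE4 = -357.1)

#' Construct a GroupSpec
#'
#' Builds one experimental group for the synthetic cohort generator. For the
#' built-in group names (`"APOEKO"`, `"APOE2"`, `"APOE3"`, `"APOE4"`)
#' unsupplied parameters take the group's default study-like values; any
#' parameter may be overridden. `treatment = "PLX3397"` multiplies
#' `microgliaBaseDensity` and `paRecruitmentCoeff` by the group's residual
#' microglia fraction (17% / 23% / 13% for the APOE2/3/4-like groups) and adds
#' `abetaTreatmentOffset` to the dose-response intercept.
#'
#' @param name group name.
#' @param treatment `"none"` (default) or `"PLX3397"`.
#' @param abetaTreatmentOffset additive A-beta-42 shift under treatment; when
#'   `NULL` (default) a treated built-in group takes its study-like shift
#'   (-148.2 for APOE2, -28.53 for APOE3, -357.1 for APOE4), untreated groups 0.
#' @param ... any [GroupSpec-class] generative slot to override.
#' @return a [GroupSpec-class].
#' @examples
#' e4 <- groupSpec("APOE4")
#' e4@abetaSlope
#' @export
groupSpec <- function(name, treatment = "none", abetaTreatmentOffset = NULL, ...) {
  if (is.null(abetaTreatmentOffset))
    abetaTreatmentOffset <- if (treatment == "PLX3397" && name %in% names(.plxAbetaOffset))
      unname(.plxAbetaOffset[name]) else 0
  base <- if (name %in% names(.groupDefaults)) .groupDefaults[[name]] else .groupDefaults[["APOE3"]]
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown GroupSpec parameters: ", paste(unknown, collapse = ", "))
  base[names(over)] <- over
  if (treatment == "PLX3397") {
    frac <- 1 - unname(.plxDepletion[name])
    if (is.na(frac)) frac <- 0.2
    if (!"microgliaBaseDensity" %in% names(over))
      base$microgliaBaseDensity <- base$microgliaBaseDensity * frac
    if (!"paRecruitmentCoeff" %in% names(over))
      base$paRecruitmentCoeff <- base$paRecruitmentCoeff * frac
  }
  new("GroupSpec",
    name = name, treatment = treatment,
    plaqueDensity = base$plaqueDensity,
    plaqueDiameterMeanlog = base$plaqueDiameterMeanlog,
    plaqueDiameterSdlog = base$plaqueDiameterSdlog,
    coreFractionShape1 = base$coreFractionShape1,
    coreFractionShape2 = base$coreFractionShape2,
    apoeMeanlog = base$apoeMeanlog, apoeSdlog = base$apoeSdlog,
    abetaSlope = base$abetaSlope, abetaIntercept = base$abetaIntercept,
    abetaNoiseSd = base$abetaNoiseSd,
    abetaTreatmentOffset = abetaTreatmentOffset,
    microgliaBaseDensity = base$microgliaBaseDensity,
    paRecruitmentCoeff = base$paRecruitmentCoeff,
    migrationCoeff = base$migrationCoeff,
    spotRate = base$spotRate
  )
}

#' Construct a CohortConfig
#'
#' @param groups list of [GroupSpec-class]; default the four study-like groups.
#' @param micePerGroup mice per group (default 8).
#' @param fovsPerMouse imaged fields per mouse (default 3).
#' @param pixelSizeUm calibration of generated fields (default 0.43).
#' @param fovSizeUm field size (default 438.88, the 40x field).
#' @param seed integer cohort seed.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(groups = lapply(c("APOEKO", "APOE2", "APOE3", "APOE4"), groupSpec),
                         micePerGroup = 8L, fovsPerMouse = 3L,
                         pixelSizeUm = 0.43, fovSizeUm = 438.88, seed = 1L) {
  new("CohortConfig",
    groups = groups, micePerGroup = as.integer(micePerGroup),
    fovsPerMouse = as.integer(fovsPerMouse),
    pixelSizeUm = pixelSizeUm, fovSizeUm = fovSizeUm, seed = as.integer(seed)
  )
}

#' Construct a FeatureBankConfig
#'
#' @param bank `"plaque"` (sigmas 1,2,4,8; 6 planes per sigma) or
#'   `"microglia"` (sigmas 2,4,8,16,32,64; adds mean and max filters), or
#'   `"custom"` with explicit `sigmas`/`filters`.
#' @param sigmas,filters explicit configuration when `bank = "custom"`.
#' @return a [FeatureBankConfig-class].
#' @examples
#' nFeatures(featureBank("plaque"))    # 25
#' nFeatures(featureBank("microglia")) # 49
#' @export
featureBank <- function(bank = c("plaque", "microglia", "custom"),
                        sigmas = NULL, filters = NULL) {
  bank <- match.arg(bank)
  if (bank == "plaque") {
    sigmas <- 2^(0:3)
    filters <- c("gaussian", "dog", "gradient_magnitude", "log", "hessian_eig")
  } else if (bank == "microglia") {
    sigmas <- 2^(1:6)
    filters <- c("gaussian", "dog", "gradient_magnitude", "log", "hessian_eig",
                 "mean", "max")
  } else {
    if (is.null(sigmas) || is.null(filters))
      stop("custom bank requires sigmas and filters")
  }
  new("FeatureBankConfig", sigmas = as.numeric(sigmas), filters = filters)
}

#' Construct a FusionConfig
#' @param wSoma,wProc distance-map weights (soma must dominate).
#' @param bodyRadiusUm body/process split threshold (um).
#' @param closingRadiusPx process-mask closing radius (px).
#' @return a [FusionConfig-class].
#' @export
fusionConfig <- function(wSoma = 2, wProc = 1, bodyRadiusUm = 3, closingRadiusPx = 2) {
  new("FusionConfig", wSoma = wSoma, wProc = wProc,
      bodyRadiusUm = bodyRadiusUm, closingRadiusPx = closingRadiusPx)
}

#' Construct a SpotDetectionConfig
#' @param dogSigmaPx band-pass scale (px).
#' @param brightnessK MAD multiplier for the brightness threshold.
#' @param minAreaPx,maxAreaPx component area window (px).
#' @param minSeparationPx minimum spot separation (px).
#' @return a [SpotDetectionConfig-class].
#' @export
spotConfig <- function(dogSigmaPx = 1.5, brightnessK = 5, minAreaPx = 2,
                       maxAreaPx = 50, minSeparationPx = 3) {
  new("SpotDetectionConfig", dogSigmaPx = dogSigmaPx, brightnessK = brightnessK,
      minAreaPx = minAreaPx, maxAreaPx = maxAreaPx, minSeparationPx = minSeparationPx)
}
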