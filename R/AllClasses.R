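#' Calibrated multi-channel field of view
#'
#' A 2D multi-channel fluorescence image with per-channel role labels and a
#' physical calibration. Image matrices are indexed `[x, y]` with pixel centers
#' at integer coordinates; physical coordinates are `(px - 0.5) * pixelSize`.
#'
#' @slot pixels named list of numeric matrices (one per channel), identical dims.
#' @slot channelRoles named integer vector mapping roles
#'   (`"plaque"`, `"microglia"`, `"reporter"`, `"spots"`, ...) to list indices.
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot fovSizeUm physical field extent in micrometres (square field).
#'
#' @details The default field sizes follow standard confocal objectives:
#' 438.88 um at 40x, 880.42 um at 20x, 292.3 um at 60x.
#' @export
setClass("FieldOfView",
  representation(
    pixels = "list",
    channelRoles = "integer",
    pixelSizeUm = "numeric",
    fovSizeUm = "numeric"
  )
)

setValidity("FieldOfView", function(object) {
  msg <- character()
  if (length(object@pixels) == 0L) msg <- c(msg, "at least one channel required")
  dims <- lapply(object@pixels, dim)
  if (length(dims) > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "all channels must share identical dimensions")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (any(object@channelRoles < 1L) || any(object@channelRoles > length(object@pixels)))
    msg <- c(msg, "channelRoles indices out of range")
  if (length(dims) > 0L) {
    n <- dims[[1]][1]
    if (abs(n * object@pixelSizeUm - object@fovSizeUm) > object@pixelSizeUm)
      msg <- c(msg, "pixel count x pixel size must equal fovSizeUm within one pixel")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth for a synthetic field of view
#'
#' Instance-level truth emitted alongside each generated image: plaque and
#' microglia label images, per-instance tables, branch polylines and spot
#' positions.
#'
#' @slot plaqueLabels integer matrix, 0 = background, k = plaque k.
#' @slot plaqueTable data.frame: `plaque_id, cx_px, cy_px, radius_um, core_fraction`.
#' @slot microgliaLabels integer matrix of microglia instances.
#' @slot microgliaTable data.frame: `cell_id, soma_x_px, soma_y_px,
#'   soma_radius_um, process_length_um, plaque_associated`.
#' @slot branches list (per cell) of branch polylines (2-column px matrices).
#' @slot spotPositions 2-column matrix of (x, y) spot centres in px.
#' @export
setClass("GroundTruth",
  representation(
    plaqueLabels = "matrix",
    plaqueTable = "data.frame",
    microgliaLabels = "matrix",
    microgliaTable = "data.frame",
    branches = "list",
    spotPositions = "matrix"
  )
)

#' Per-group generative parameters for the synthetic cohort
#'
#' One experimental group of the synthetic cohort generator. Defaults are
#' produced by [groupSpec()] which carries the built-in APOEKO / APOE2 /
#' APOE3 / APOE4-like parameterisations.
#'
#' @slot name group label.
#' @slot treatment `"none"` or `"PLX3397"` (microglia depletion).
#' @slot plaqueDensity expected plaques per field (Poisson mean).
#' @slot plaqueDiameterMeanlog,plaqueDiameterSdlog log-normal plaque diameter (um).
#' @slot coreFractionShape1,coreFractionShape2 Beta parameters of the compact
#'   core fraction in `[0, 1]`.
#' @slot apoeMeanlog,apoeSdlog log-normal APOE level (arbitrary ELISA units).
#' @slot abetaSlope,abetaIntercept,abetaNoiseSd linear dose-response of
#'   guanidine-soluble A-beta-42 on APOE level.
#' @slot abetaTreatmentOffset additive shift of A-beta-42 under treatment.
#' @slot microgliaBaseDensity expected background microglia per field.
#' @slot paRecruitmentCoeff extra plaque-associated cells per unit plaque area
#'   fraction.
#' @slot migrationCoeff probability per unit plaque area fraction that a
#'   background cell relocates to a plaque edge (capped at 0.85); makes the
#'   non-plaque-associated density decline gently as plaque load grows while
#'   the plaque-associated population rises.
#' @slot spotRate expected SiMPull spots per frame.
#' @export
setClass("GroupSpec",
  representation(
    name = "character",
    treatment = "character",
    plaqueDensity = "numeric",
    plaqueDiameterMeanlog = "numeric",
    plaqueDiameterSdlog = "numeric",
    coreFractionShape1 = "numeric",
    coreFractionShape2 = "numeric",
    apoeMeanlog = "numeric",
    apoeSdlog = "numeric",
    abetaSlope = "numeric",
    abetaIntercept = "numeric",
    abetaNoiseSd = "numeric",
    abetaTreatmentOffset = "numeric",
    microgliaBaseDensity = "numeric",
    paRecruitmentCoeff = "numeric",
    migrationCoeff = "numeric",
    spotRate = "numeric"
  )
)

setValidity("GroupSpec", function(object) {
  msg <- character()
  for (s in c("plaqueDensity", "microgliaBaseDensity", "paRecruitmentCoeff",
              "migrationCoeff", "spotRate"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
  if (object@coreFractionShape1 <= 0 || object@coreFractionShape2 <= 0)
    msg <- c(msg, "core fraction Beta parameters must be positive")
  if (!object@treatment %in% c("none", "PLX3397"))
    msg <- c(msg, "treatment must be 'none' or 'PLX3397'")
  if (length(msg)) msg else TRUE
})

#' Cohort-level generative configuration
#'
#' @slot groups list of [GroupSpec-class] objects.
#' @slot micePerGroup number of mice per group (>= 1).
#' @slot fovsPerMouse fields of view imaged per mouse (default 3).
#' @slot pixelSizeUm image calibration for generated fields.
#' @slot fovSizeUm physical field size (um).
#' @slot seed integer seed for the whole cohort.
#' @export
setClass("CohortConfig",
  representation(
    groups = "list",
    micePerGroup = "integer",
    fovsPerMouse = "integer",
    pixelSizeUm = "numeric",
    fovSizeUm = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@micePerGroup < 1L) msg <- c(msg, "micePerGroup must be >= 1")
  if (object@fovsPerMouse < 1L) msg <- c(msg, "fovsPerMouse must be >= 1")
  if (!all(vapply(object@groups, is, logical(1), "GroupSpec")))
    msg <- c(msg, "groups must all be GroupSpec objects")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (length(msg)) msg else TRUE
})

#' Multi-scale filter bank configuration
#'
#' Scales and filter families of the trainable pixel classifier. The plaque
#' bank uses sigma in {1, 2, 4, 8} with gaussian, difference-of-gaussians,
#' gradient magnitude, Laplacian-of-gaussian and the two Hessian eigenvalues;
#' the microglia bank uses sigma in {2, 4, 8, 16, 32, 64} and adds mean and
#' max filters. The raw image is always included once as the identity plane.
#'
#' @slot sigmas strictly increasing scales in pixels.
#' @slot filters character subset of `"gaussian"`, `"dog"`,
#'   `"gradient_magnitude"`, `"log"`, `"hessian_eig"`, `"mean"`, `"max"`.
#' @export
setClass("FeatureBankConfig",
  representation(sigmas = "numeric", filters = "character")
)

setValidity("FeatureBankConfig", function(object) {
  msg <- character()
  if (is.unsorted(object@sigmas, strictly = TRUE))
    msg <- c(msg, "sigmas must be strictly increasing")
  if (any(object@sigmas <= 0)) msg <- c(msg, "sigmas must be positive")
  known <- c("gaussian", "dog", "gradient_magnitude", "log", "hessian_eig", "mean", "max")
  if (!all(object@filters %in% known))
    msg <- c(msg, paste("unknown filters:", paste(setdiff(object@filters, known), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Trained random-forest pixel classifier
#'
#' @slot forest the fitted randomForest model.
#' @slot bank the [FeatureBankConfig-class] used at training time.
#' @slot nFeatures number of feature planes expected at prediction.
#' @export
setClass("PixelClassifier",
  representation(forest = "ANY", bank = "FeatureBankConfig", nFeatures = "integer")
)

#' Distance-transform fusion configuration
#'
#' Parameters of the microglia instance-segmentation fusion: the semantic mask
#' and the soma mask are both Euclidean-distance transformed and combined as
#' `wProc * EDT(mask) + wSoma * EDT(soma)`; soma areas must dominate
#' (`wSoma > wProc`). `bodyRadiusUm` is the thickness threshold splitting cell
#' bodies from processes; `closingRadiusPx` repairs small process
#' discontinuities by morphological closing.
#'
#' @slot wSoma soma-distance weight (default 2).
#' @slot wProc full-mask distance weight (default 1).
#' @slot bodyRadiusUm body/process EDT split threshold in um (default 3).
#' @slot closingRadiusPx disk radius of the process-mask closing (default 2).
#' @export
setClass("FusionConfig",
  representation(
    wSoma = "numeric", wProc = "numeric",
    bodyRadiusUm = "numeric", closingRadiusPx = "numeric"
  )
)

setValidity("FusionConfig", function(object) {
  msg <- character()
  if (!(object@wSoma > object@wProc && object@wProc > 0))
    msg <- c(msg, "weights must satisfy wSoma > wProc > 0")
  if (object@bodyRadiusUm <= 0) msg <- c(msg, "bodyRadiusUm must be positive")
  if (object@closingRadiusPx < 0) msg <- c(msg, "closingRadiusPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Spot-detection configuration for SiMPull frames
#'
#' Difference-of-gaussian band-pass, robust brightness threshold at
#' `median + k * MAD`, area window and local-maxima deduplication; the same
#' configuration is applied to every frame of an experiment.
#'
#' @slot dogSigmaPx band-pass centre scale (default 1.5 px).
#' @slot brightnessK MAD multiplier of the brightness threshold (default 5).
#' @slot minAreaPx,maxAreaPx component area window (defaults 2, 50).
#' @slot minSeparationPx minimum centre separation (default 3 px).
#' @export
setClass("SpotDetectionConfig",
  representation(
    dogSigmaPx = "numeric", brightnessK = "numeric",
    minAreaPx = "numeric", maxAreaPx = "numeric", minSeparationPx = "numeric"
  )
)

setValidity("SpotDetectionConfig", function(object) {
  msg <- character()
  if (object@minAreaPx > object@maxAreaPx) msg <- c(msg, "minAreaPx must be <= maxAreaPx")
  if (object@brightnessK <= 0) msg <- c(msg, "brightnessK must be positive")
  if (length(msg)) msg else TRUE
})
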