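# Cohort generator: per-mouse APOE level and guanidine-soluble A-beta-42 from
# a genotype-specific linear dose-response, with the mouse's plaque load
# scaled by its A-beta-42 relative to the group expectation.

expectedAbeta <- function(spec) {
  apoeMean <- exp(spec@apoeMeanlog + spec@apoeSdlog^2 / 2)
  off <- if (spec@treatment == "PLX3397") spec@abetaTreatmentOffset else 0
  spec@abetaIntercept + off + spec@abetaSlope * apoeMean
}

#' Generate a synthetic cohort of mice with imaged fields and a cohort table
#'
#' For each mouse the APOE level is drawn from the group's log-normal, the
#' A-beta-42 level follows the group's linear dose-response plus Gaussian
#' noise, and the plaque density of that mouse's fields scales with its
#' A-beta-42 relative to the group expectation. Each field is generated with
#' [generateFov()] under a child seed drawn from the cohort stream, so the
#' whole cohort is reproducible from `config@seed`.
#'
#' @param config a [CohortConfig-class].
#' @param renderImages generate pixel data (`TRUE`, default) or ground truth
#'   and tables only (fast path for statistical work at scale).
#' @param ... further arguments passed to [generateFov()] (noise levels,
#'   association threshold).
#' @return `list(fovs = <list of per-field records>, table = <per-mouse
#'   data.frame>, fovTable = <per-field data.frame>)`. Each `fovs` element is
#'   `list(fov, truth, group, treatment, mouse_id, fov_id)` (`fov` is `NULL`
#'   when `renderImages = FALSE`). The mouse table carries
#'   `group, treatment, mouse_id, apoe_level, abeta42` and ground-truth
#'   per-field aggregates averaged over the mouse's fields.
#' @export
generateCohort <- function(config, renderImages = TRUE, ...) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, {
    fovs <- list()
    mouseRows <- list()
    fovRows <- list()
    mouseCounter <- 0L
    for (spec in config@groups) {
      validObject(spec)
      eAb <- expectedAbeta(spec)
      off <- if (spec@treatment == "PLX3397") spec@abetaTreatmentOffset else 0
      for (m in seq_len(config@micePerGroup)) {
        mouseCounter <- mouseCounter + 1L
        mouseId <- sprintf("%s_%s_m%02d", spec@name,
                           if (spec@treatment == "none") "ctrl" else "plx", m)
        apoe <- if (is.finite(spec@apoeMeanlog))
          rlnorm(1, spec@apoeMeanlog, spec@apoeSdlog) else 0
        abeta <- spec@abetaIntercept + off + spec@abetaSlope * apoe +
          rnorm(1, 0, spec@abetaNoiseSd)
        loadFactor <- if (eAb > 0) max(abeta / eAb, 0) else 1
        mouseSpec <- spec
        mouseSpec@plaqueDensity <- spec@plaqueDensity * loadFactor
        agg <- list(n_plaques = 0, plaque_area_fraction = 0, n_microglia = 0,
                    n_pa = 0, n_nonpa = 0)
        for (f in seq_len(config@fovsPerMouse)) {
          childSeed <- sample.int(.Machine$integer.max - 1L, 1L)
          if (renderImages) {
            g <- generateFov(mouseSpec, seed = childSeed,
                             pixelSizeUm = config@pixelSizeUm,
                             fovSizeUm = config@fovSizeUm, ...)
          } else {
            g <- withSeed(childSeed, generateGroundTruthOnly(
              mouseSpec, config@pixelSizeUm, config@fovSizeUm, ...))
          }
          tr <- g$truth
          af <- sum(pi * tr@plaqueTable$radius_um^2) / config@fovSizeUm^2
          nPa <- sum(tr@microgliaTable$plaque_associated)
          fovs[[length(fovs) + 1L]] <- list(
            fov = g$fov, truth = tr, group = spec@name,
            treatment = spec@treatment, mouse_id = mouseId, fov_id = f
          )
          fovRows[[length(fovRows) + 1L]] <- data.frame(
            group = spec@name, treatment = spec@treatment, mouse_id = mouseId,
            fov_id = f, n_plaques = nrow(tr@plaqueTable),
            plaque_area_fraction = af,
            n_microglia = nrow(tr@microgliaTable), n_pa = nPa,
            n_nonpa = nrow(tr@microgliaTable) - nPa
          )
          agg$n_plaques <- agg$n_plaques + nrow(tr@plaqueTable)
          agg$plaque_area_fraction <- agg$plaque_area_fraction + af
          agg$n_microglia <- agg$n_microglia + nrow(tr@microgliaTable)
          agg$n_pa <- agg$n_pa + nPa
          agg$n_nonpa <- agg$n_nonpa + (nrow(tr@microgliaTable) - nPa)
        }
        k <- config@fovsPerMouse
        mouseRows[[mouseCounter]] <- data.frame(
          group = spec@name, treatment = spec@treatment, mouse_id = mouseId,
          apoe_level = apoe, abeta42 = abeta,
          n_plaques = agg$n_plaques / k,
          plaque_area_fraction = agg$plaque_area_fraction / k,
          n_microglia = agg$n_microglia / k, n_pa = agg$n_pa / k,
          n_nonpa = agg$n_nonpa / k
        )
      }
    }
    list(fovs = fovs, table = do.call(rbind, mouseRows),
         fovTable = do.call(rbind, fovRows))
  })
}

# Ground truth without pixel rendering: same instance-level draws as
# generateFov's placement model, but no channels. Used at statistical scale.
generateGroundTruthOnly <- function(spec, pixelSizeUm, fovSizeUm,
                                    associationUm = 5, ...) {
  n <- as.integer(round(fovSizeUm / pixelSizeUm))
  truth <- emptyGroundTruth(0L, 0L)
  nPlaques <- rpois(1L, spec@plaqueDensity)
  if (nPlaques > 0) {
    radiusUm <- pmin(rlnorm(nPlaques, spec@plaqueDiameterMeanlog,
                            spec@plaqueDiameterSdlog) / 2, 0.45 * fovSizeUm)
    cf <- rbeta(nPlaques, spec@coreFractionShape1, spec@coreFractionShape2)
    rPx <- radiusUm / pixelSizeUm
    truth@plaqueTable <- data.frame(
      plaque_id = seq_len(nPlaques),
      cx_px = runif(nPlaques, rPx + 1, n - rPx),
      cy_px = runif(nPlaques, rPx + 1, n - rPx),
      radius_um = radiusUm, core_fraction = cf
    )
  }
  areaFraction <- sum(pi * truth@plaqueTable$radius_um^2) / fovSizeUm^2
  nBg <- rpois(1L, spec@microgliaBaseDensity)
  nPa <- if (nPlaques > 0) rpois(1L, spec@paRecruitmentCoeff * areaFraction) else 0L
  centers <- placeSomata(nBg, nPa, truth@plaqueTable, n, pixelSizeUm,
                         associationUm, spec@migrationCoeff, areaFraction)
  nCells <- nrow(centers)
  if (nCells > 0) {
    assoc <- rep(FALSE, nCells)
    if (nPlaques > 0) {
      for (k in seq_len(nCells)) {
        dc <- sqrt((truth@plaqueTable$cx_px - centers[k, 1])^2 +
                   (truth@plaqueTable$cy_px - centers[k, 2])^2) * pixelSizeUm
        assoc[k] <- any(dc - truth@plaqueTable$radius_um <= associationUm)
      }
    }
    truth@microgliaTable <- data.frame(
      cell_id = seq_len(nCells), soma_x_px = centers[, 1],
      soma_y_px = centers[, 2], soma_radius_um = runif(nCells, 3.2, 4.8),
      process_length_um = NA_real_, plaque_associated = assoc
    )
  }
  list(fov = NULL, truth = truth)
}
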