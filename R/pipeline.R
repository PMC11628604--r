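# Orchestration: validate a run configuration, execute
# simulate -> measure -> test, and write tables, a machine-readable summary
# and a run log.

runConfigDefaults <- list(
  groups = c("APOEKO", "APOE2", "APOE3", "APOE4"),
  mice_per_group = 6L,
  fovs_per_mouse = 3L,
  pixel_size_um = 0.43,
  fov_size_um = 438.88,
  association_um = 5,
  render_images = TRUE,
  plaque_threshold = 0.05,
  fusion = list(w_soma = 2, w_proc = 1, body_radius_um = 3, closing_radius_px = 2),
  spots = list(dog_sigma_px = 1.5, brightness_k = 5, min_area_px = 2,
               max_area_px = 50, min_separation_px = 3),
  simpull = list(mice_per_group = 4L, replicates = 3L, frames_per_replicate = 9L,
                 frame_px = 256L, snr = 10),
  analyses = c("dose_response", "microglia_load", "spots"),
  seed = 1L
)

#' Validate and normalize a pipeline run configuration
#'
#' Accepts a YAML/JSON path or a list; fills documented defaults (warning
#' when the pixel size is filled), checks units and cross-field constraints,
#' and reports every violation with its field path.
#'
#' @param config list, or path to a YAML or JSON file.
#' @return the normalized configuration list.
#' @examples
#' cfg <- validateRunConfig(list(mice_per_group = 4, pixel_size_um = 1.72))
#' cfg$association_um
#' @export
validateRunConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(runConfigDefaults))
  errs <- character()
  if (length(unknown))
    errs <- c(errs, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  if (!"pixel_size_um" %in% names(config))
    warning("pixel_size_um missing: filled with default 0.43 um")
  for (f in names(runConfigDefaults)) {
    if (!f %in% names(config)) {
      config[[f]] <- runConfigDefaults[[f]]
    } else if (is.list(runConfigDefaults[[f]]) && is.list(config[[f]])) {
      miss <- setdiff(names(runConfigDefaults[[f]]), names(config[[f]]))
      config[[f]][miss] <- runConfigDefaults[[f]][miss]
    }
  }
  if (config$pixel_size_um <= 0) errs <- c(errs, "pixel_size_um: must be > 0")
  if (config$association_um < 0) errs <- c(errs, "association_um: must be >= 0")
  if (!(config$fusion$w_soma > config$fusion$w_proc && config$fusion$w_proc > 0))
    errs <- c(errs, "fusion.w_soma/w_proc: weights must satisfy w_soma > w_proc > 0")
  if (config$mice_per_group < 1) errs <- c(errs, "mice_per_group: must be >= 1")
  if (config$fovs_per_mouse < 1) errs <- c(errs, "fovs_per_mouse: must be >= 1")
  bad <- setdiff(config$analyses, c("dose_response", "microglia_load", "spots", "treatment"))
  if (length(bad))
    errs <- c(errs, paste0("analyses: unknown ", paste(bad, collapse = ", ")))
  if (length(errs)) stop("invalid run configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  config$mice_per_group <- as.integer(config$mice_per_group)
  config$fovs_per_mouse <- as.integer(config$fovs_per_mouse)
  config$seed <- as.integer(config$seed)
  config
}

stageSeed <- function(seed, stage) {
  # deterministic per-stage child seed: offset by a stage-name character hash
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% (.Machine$integer.max - 1)) + 1L
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full simulate - measure - test pipeline
#'
#' Generates the configured cohort, measures every field (plaque threshold
#' and segmentation, soma detection, plaque-association classification),
#' runs the configured analyses, and writes per-stage CSVs, a summary JSON
#' and a run log into `outDir`. Reruns with the same configuration produce
#' an identical summary.
#'
#' @param config run configuration (list or file path, see
#'   [validateRunConfig()]).
#' @param outDir output directory.
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("gliaquant_run")) {
  config <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  configEcho <- config
  configEcho$groups <- vapply(config$groups, function(g)
    if (is(g, "GroupSpec")) paste0(g@name, "/", g@treatment) else as.character(g),
    character(1))
  log <- c(paste("gliaQuant", as.character(utils::packageVersion("gliaQuant"))),
           paste("R", paste(R.version$major, R.version$minor, sep = ".")),
           paste("seed", config$seed),
           paste("config:", jsonlite::toJSON(configEcho, auto_unbox = TRUE)))
  summary <- list(seed = config$seed)

  cohort <- runStage("simulate", {
    groups <- lapply(config$groups, function(g)
      if (is(g, "GroupSpec")) g else groupSpec(g))
    cc <- cohortConfig(groups = groups, micePerGroup = config$mice_per_group,
                       fovsPerMouse = config$fovs_per_mouse,
                       pixelSizeUm = config$pixel_size_um,
                       fovSizeUm = config$fov_size_um,
                       seed = stageSeed(config$seed, "simulate"))
    generateCohort(cc, renderImages = config$render_images,
                   associationUm = config$association_um)
  })
  write.csv(cohort$table, file.path(outDir, "cohort_mice.csv"), row.names = FALSE)

  fovSummaries <- runStage("measure", {
    if (config$render_images) {
      rows <- lapply(cohort$fovs, function(rec) {
        ch <- getChannel(rec$fov, "plaque")
        pm <- suppressWarnings(thresholdPlaques(ch, config$plaque_threshold))
        seg <- segmentPlaques(pm, config$pixel_size_um)
        ps <- summarizeFovPlaques(seg$records, fovSize(rec$fov)^2)
        som <- detectSomata(getChannel(rec$fov, "microglia"), config$pixel_size_um)
        assoc <- classifyAssociation(som$centroids, seg$labels > 0,
                                     config$pixel_size_um, config$association_um)
        nPa <- sum(assoc$association == "plaque_associated")
        data.frame(group = rec$group, treatment = rec$treatment,
                   mouse_id = rec$mouse_id, fov_id = rec$fov_id,
                   n_plaques = ps$n_plaques, area_fraction = ps$area_fraction,
                   n_microglia = nrow(som$centroids), n_pa = nPa,
                   n_nonpa = nrow(som$centroids) - nPa)
      })
      do.call(rbind, rows)
    } else {
      df <- cohort$fovTable
      names(df)[names(df) == "plaque_area_fraction"] <- "area_fraction"
      df
    }
  })
  write.csv(fovSummaries, file.path(outDir, "fov_summaries.csv"), row.names = FALSE)

  perMouse <- runStage("aggregate", {
    agg <- aggregate(cbind(n_plaques, area_fraction, n_microglia, n_pa, n_nonpa)
                     ~ group + treatment + mouse_id, data = fovSummaries, FUN = mean)
    merge(cohort$table[, c("group", "treatment", "mouse_id", "apoe_level", "abeta42")],
          agg, by = c("group", "treatment", "mouse_id"))
  })
  write.csv(perMouse, file.path(outDir, "per_mouse.csv"), row.names = FALSE)

  if ("dose_response" %in% config$analyses) {
    summary$apoe_dose_response <- runStage("dose_response", {
      res <- lapply(split(perMouse, perMouse$group), function(d) {
        if (nrow(d) < 3 || sd(d$apoe_level) < 1e-12) return(NULL)
        r <- olsFit(d$apoe_level, d$abeta42)
        data.frame(group = d$group[1], slope = r$slope, r_squared = r$r_squared,
                   p = r$p, n = r$n)
      })
      do.call(rbind, Filter(Negate(is.null), res))
    })
  }

  if ("microglia_load" %in% config$analyses) {
    summary$microglia_vs_plaque_load <- runStage("microglia_load", {
      ctrl <- perMouse[perMouse$treatment == "none", ]
      if (sd(ctrl$area_fraction) < 1e-12) {
        log <- c(log, "microglia_load skipped: no variation in plaque area fraction")
        NULL
      } else {
        fits <- list(total = olsFit(ctrl$area_fraction, ctrl$n_microglia),
                     pa = olsFit(ctrl$area_fraction, ctrl$n_pa),
                     nonpa = olsFit(ctrl$area_fraction, ctrl$n_nonpa))
        data.frame(population = names(fits),
                   slope = vapply(fits, `[[`, numeric(1), "slope"),
                   r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                   p = vapply(fits, `[[`, numeric(1), "p"),
                   n = nrow(ctrl))
      }
    })
  }

  if ("spots" %in% config$analyses) {
    summary$simpull <- runStage("spots", {
      sp <- config$simpull
      counts <- list()
      sseed <- stageSeed(config$seed, "spots")
      groups <- lapply(config$groups, function(g)
        if (is(g, "GroupSpec")) g else groupSpec(g))
      for (spec in groups) {
        for (m in seq_len(sp$mice_per_group)) {
          for (r in seq_len(sp$replicates)) for (f in seq_len(sp$frames_per_replicate)) {
            sseed <- sseed + 1L
            g <- generateSimpullFov(spec, seed = sseed, framePx = sp$frame_px,
                                    snr = sp$snr)
            det <- detectSpots(getChannel(g$fov, "spots"),
                               spotConfig(config$spots$dog_sigma_px,
                                          config$spots$brightness_k,
                                          config$spots$min_area_px,
                                          config$spots$max_area_px,
                                          config$spots$min_separation_px))
            counts[[length(counts) + 1L]] <- data.frame(
              group = spec@name, mouse_id = paste0(spec@name, "_m", m),
              replicate_id = paste0("r", r), frame_id = f, n_spots = det$n_spots)
          }
        }
      }
      counts <- do.call(rbind, counts)
      write.csv(counts, file.path(outDir, "spot_counts.csv"), row.names = FALSE)
      agg <- aggregateCounts(counts)
      byMouse <- merge(agg$byMouse,
                       unique(counts[, c("group", "mouse_id")]), by = "mouse_id")
      an <- anovaTukey(split(byMouse$mean_spots, byMouse$group))
      list(per_mouse = byMouse, anova_f = an$f, anova_p = an$p, tukey = an$tukey)
    })
  }

  if ("treatment" %in% config$analyses) {
    summary$treatment_effect <- runStage("treatment", {
      res <- lapply(split(perMouse, perMouse$group), function(d) {
        if (length(unique(d$treatment)) < 2) return(NULL)
        r <- multipleRegression(d$abeta42, d$treatment == "PLX3397", d$apoe_level)
        data.frame(group = d$group[1], beta_treatment = r$beta_treatment,
                   se = r$se_treatment, p = r$p_treatment, n = r$n)
      })
      do.call(rbind, Filter(Negate(is.null), res))
    })
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(summary)
}
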