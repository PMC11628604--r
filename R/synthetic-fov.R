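# Synthetic field-of-view generator.
#
# Plaques are rendered as radial profiles: a bright homogeneous core disk of
# radius core_fraction * R over a speckled decaying halo out to R, so that the
# core fraction is a monotone knob for texture compactness (ASM). Microglia
# are somata (disks, later blurred) with 3-6 branched processes simulated as
# 8-neighbour random walks of known summed length. Plaque-associated cells are
# placed within 5 um of plaque edges at a rate proportional to the plaque area
# fraction; background cells are uniform. Noise is Poisson shot noise plus
# additive Gaussian read noise.

renderDisk <- function(canvas, cx, cy, radiusPx, value, accumulate = FALSE) {
  nx <- nrow(canvas); ny <- ncol(canvas)
  x0 <- max(1L, floor(cx - radiusPx)); x1 <- min(nx, ceiling(cx + radiusPx))
  y0 <- max(1L, floor(cy - radiusPx)); y1 <- min(ny, ceiling(cy + radiusPx))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  r2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  sel <- r2 <= radiusPx^2
  patch <- canvas[xs, ys, drop = FALSE]
  patch[sel] <- if (accumulate) patch[sel] + value else value
  canvas[xs, ys] <- patch
  canvas
}

renderPlaque <- function(channel, labels, id, cx, cy, radiusPx, coreFraction,
                         amplitude = 0.9, speckleLow = 0.3) {
  nx <- nrow(channel); ny <- ncol(channel)
  x0 <- max(1L, floor(cx - radiusPx)); x1 <- min(nx, ceiling(cx + radiusPx))
  y0 <- max(1L, floor(cy - radiusPx)); y1 <- min(ny, ceiling(cy + radiusPx))
  xs <- x0:x1; ys <- y0:y1
  r <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  inside <- r <= radiusPx
  core <- r <= coreFraction * radiusPx
  halo <- inside & !core
  patch <- channel[xs, ys, drop = FALSE]
  patch[core] <- pmax(patch[core], amplitude)
  if (any(halo)) {
    # decaying rim intensity times a continuous speckle field: the halo is
    # granular (wide intensity spread), the core homogeneous; the rim floor
    # stays a few noise SDs above background so the stained extent matches
    # the nominal disk
    hw <- (r[halo] - coreFraction * radiusPx) / pmax(radiusPx * (1 - coreFraction), 1e-6)
    base <- amplitude * (1 - 0.7 * hw)
    speck <- runif(sum(halo), speckleLow, 1)
    patch[halo] <- pmax(patch[halo], base * speck)
  }
  channel[xs, ys] <- patch
  lpatch <- labels[xs, ys, drop = FALSE]
  free <- inside & lpatch == 0L
  lpatch[free] <- id
  labels[xs, ys] <- lpatch
  list(channel = channel, labels = labels)
}

# 8-neighbour persistent random walk from (x0, y0); returns polyline (px) and
# its summed Euclidean step length (px).
walkBranch <- function(x0, y0, nSteps, nx, ny) {
  dirs <- cbind(
    dx = c(1, 1, 0, -1, -1, -1, 0, 1),
    dy = c(0, 1, 1, 1, 0, -1, -1, -1)
  )
  d <- sample.int(8L, 1L)
  pts <- matrix(0, nSteps + 1L, 2L)
  pts[1L, ] <- c(x0, y0)
  len <- 0
  for (s in seq_len(nSteps)) {
    # persistence: mostly straight, occasional 45-degree turns
    turn <- sample(c(-1L, 0L, 1L), 1L, prob = c(0.15, 0.7, 0.15))
    d <- ((d - 1L + turn) %% 8L) + 1L
    nxt <- pts[s, ] + dirs[d, ]
    if (nxt[1] < 1 || nxt[1] > nx || nxt[2] < 1 || nxt[2] > ny) {
      pts <- pts[seq_len(s), , drop = FALSE]
      return(list(points = pts, lengthPx = len))
    }
    pts[s + 1L, ] <- nxt
    len <- len + sqrt(sum(dirs[d, ]^2))
  }
  list(points = pts, lengthPx = len)
}

applyNoise <- function(channel, photonsPerUnit = 600, readNoiseSd = 0.01) {
  out <- channel
  if (photonsPerUnit > 0) {
    counts <- rpois(length(channel), pmax(channel, 0) * photonsPerUnit)
    out <- matrix(counts / photonsPerUnit, nrow(channel), ncol(channel))
  }
  if (readNoiseSd > 0)
    out <- out + matrix(rnorm(length(channel), 0, readNoiseSd),
                        nrow(channel), ncol(channel))
  out
}

#' Generate a synthetic multi-channel field of view with ground truth
#'
#' Renders plaque, microglia and reporter channels for one field under a
#' [GroupSpec-class], together with instance-level [GroundTruth-class].
#' Identical `(spec, seed)` yield bit-identical output.
#'
#' @param spec a [GroupSpec-class].
#' @param seed integer seed.
#' @param pixelSizeUm calibration (default 0.43 um/px).
#' @param fovSizeUm field size (default 438.88 um, the 40x field).
#' @param photonsPerUnit Poisson shot-noise scale (photons per intensity unit;
#'   0 disables shot noise).
#' @param readNoiseSd additive Gaussian read-noise SD.
#' @param associationUm plaque-association distance used for ground-truth
#'   flags (default 5 um).
#' @param channels which channels to render (subset of `"plaque"`,
#'   `"microglia"`, `"reporter"`); ground truth always covers all instances.
#'   Restricting channels changes the RNG stream, so determinism holds per
#'   `(spec, seed, channels)`.
#' @return `list(fov = FieldOfView, truth = GroundTruth)`.
#' @examples
#' g <- generateFov(groupSpec("APOE4", plaqueDensity = 3), seed = 1,
#'                  pixelSizeUm = 1.72)
#' g$fov
#' g$truth
#' @export
generateFov <- function(spec, seed, pixelSizeUm = 0.43, fovSizeUm = 438.88,
                        photonsPerUnit = 600, readNoiseSd = 0.01,
                        associationUm = 5,
                        channels = c("plaque", "microglia", "reporter")) {
  stopifnot(is(spec, "GroupSpec"))
  validObject(spec)
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be positive")
  n <- as.integer(round(fovSizeUm / pixelSizeUm))
  if (n < 8L) stop("field too small for the requested calibration")
  channels <- match.arg(channels, several.ok = TRUE)
  doMicro <- "microglia" %in% channels
  withSeed(seed, {
    plaqueCh <- matrix(0, n, n)
    microCh <- matrix(0, n, n)
    reporterCh <- matrix(0, n, n)
    truth <- emptyGroundTruth(n, n)
    truth@plaqueLabels <- matrix(0L, n, n)
    truth@microgliaLabels <- matrix(0L, n, n)

    ## plaques
    nPlaques <- rpois(1L, spec@plaqueDensity)
    ptab <- vector("list", nPlaques)
    for (i in seq_len(nPlaques)) {
      radiusUm <- rlnorm(1, spec@plaqueDiameterMeanlog, spec@plaqueDiameterSdlog) / 2
      radiusUm <- min(radiusUm, 0.45 * fovSizeUm)
      cf <- rbeta(1, spec@coreFractionShape1, spec@coreFractionShape2)
      rPx <- radiusUm / pixelSizeUm
      cx <- runif(1, rPx + 1, n - rPx)
      cy <- runif(1, rPx + 1, n - rPx)
      res <- renderPlaque(plaqueCh, truth@plaqueLabels, i, cx, cy, rPx, cf)
      plaqueCh <- res$channel
      truth@plaqueLabels <- res$labels
      ptab[[i]] <- data.frame(plaque_id = i, cx_px = cx, cy_px = cy,
                              radius_um = radiusUm, core_fraction = cf)
    }
    if (nPlaques > 0) truth@plaqueTable <- do.call(rbind, ptab)
    areaFraction <- sum(pi * truth@plaqueTable$radius_um^2) / fovSizeUm^2

    ## microglia placement: hard-core background (somata tile, they do not
    ## overlap; processes may) + plaque-edge recruitment
    nBg <- rpois(1L, spec@microgliaBaseDensity)
    nPa <- if (nPlaques > 0) rpois(1L, spec@paRecruitmentCoeff * areaFraction) else 0L
    centers <- placeSomata(nBg, nPa, truth@plaqueTable, n, pixelSizeUm,
                           associationUm, spec@migrationCoeff, areaFraction)
    nCells <- nrow(centers)
    mtab <- vector("list", nCells)
    branches <- vector("list", nCells)
    for (k in seq_len(nCells)) {
      somaRUm <- runif(1, 3.2, 4.8)
      somaRPx <- somaRUm / pixelSizeUm
      lenPx <- NA_real_
      if (doMicro) {
        microCh <- renderDisk(microCh, centers[k, 1], centers[k, 2], somaRPx, 1)
        truth@microgliaLabels <- renderDiskLabel(truth@microgliaLabels,
                                                 centers[k, 1], centers[k, 2],
                                                 somaRPx, k)
        nb <- sample(3:6, 1L)
        lenPx <- 0
        cellBranches <- vector("list", nb)
        for (b in seq_len(nb)) {
          ang <- runif(1, 0, 2 * pi)
          sx <- round(centers[k, 1] + somaRPx * cos(ang))
          sy <- round(centers[k, 2] + somaRPx * sin(ang))
          sx <- min(max(sx, 1), nrow(microCh)); sy <- min(max(sy, 1), ncol(microCh))
          stepsUm <- runif(1, 12, 30)
          wb <- walkBranch(sx, sy, max(1L, round(stepsUm / pixelSizeUm)),
                           nrow(microCh), ncol(microCh))
          idx <- cbind(wb$points[, 1], wb$points[, 2])
          microCh[idx] <- pmax(microCh[idx], 0.55)
          lpx <- truth@microgliaLabels[idx]
          free <- lpx == 0L
          truth@microgliaLabels[idx[free, , drop = FALSE]] <- k
          lenPx <- lenPx + wb$lengthPx
          cellBranches[[b]] <- wb$points
        }
        branches[[k]] <- cellBranches
      }
      # true association from analytic plaque geometry
      assoc <- FALSE
      if (nPlaques > 0) {
        dc <- sqrt((truth@plaqueTable$cx_px - centers[k, 1])^2 +
                   (truth@plaqueTable$cy_px - centers[k, 2])^2) * pixelSizeUm
        edge <- dc - truth@plaqueTable$radius_um
        assoc <- any(edge <= associationUm)
      }
      mtab[[k]] <- data.frame(cell_id = k, soma_x_px = centers[k, 1],
                              soma_y_px = centers[k, 2], soma_radius_um = somaRUm,
                              process_length_um = lenPx * pixelSizeUm,
                              plaque_associated = assoc)

    }
    if (nCells > 0) truth@microgliaTable <- do.call(rbind, mtab)
    truth@branches <- branches

    chans <- list()
    if ("plaque" %in% channels)
      chans$plaque <- applyNoise(plaqueCh, photonsPerUnit, readNoiseSd)
    if (doMicro) {
      microCh <- gaussBlur(microCh, max(0.8, 1 / pixelSizeUm * 0.6))
      chans$microglia <- applyNoise(microCh, photonsPerUnit, readNoiseSd)
    }
    if ("reporter" %in% channels) {
      # smooth mottled astrocyte background
      reporterCh <- gaussBlur(matrix(runif(n * n, 0, 0.3), n, n), 4)
      chans$reporter <- applyNoise(reporterCh, photonsPerUnit, readNoiseSd)
    }
    fov <- FieldOfView(chans, pixelSizeUm = pixelSizeUm, fovSizeUm = fovSizeUm)
    list(fov = fov, truth = truth)
  })
}

# Soma centers as a hard-core (minimum-separation) point process: microglia
# tile the parenchyma, so somata essentially never overlap even though their
# processes may. Candidates violating the separation are re-drawn a bounded
# number of times, keeping the counts Poisson. Background cells migrate to a
# plaque edge with probability migrationCoeff * areaFraction, so the
# non-plaque-associated population declines gently as plaque load grows while
# the plaque-associated population rises steeply.
placeSomata <- function(nBg, nPa, plaqueTable, n, pixelSizeUm, associationUm,
                        migrationCoeff = 0, areaFraction = 0,
                        minSepUm = 12, maxTries = 40L) {
  sepPx <- minSepUm / pixelSizeUm
  centers <- matrix(numeric(), 0, 2)
  admissible <- function(p) {
    nrow(centers) == 0L ||
      all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >= sepPx^2)
  }
  drawBg <- function() c(runif(1, 6, n - 5), runif(1, 6, n - 5))
  drawPa <- function() {
    pid <- sample.int(nrow(plaqueTable), 1L, prob = plaqueTable$radius_um)
    ang <- runif(1, 0, 2 * pi)
    dUm <- runif(1, -2, associationUm - 0.5)
    rad <- (plaqueTable$radius_um[pid] + dUm) / pixelSizeUm
    c(min(max(plaqueTable$cx_px[pid] + rad * cos(ang), 6), n - 5),
      min(max(plaqueTable$cy_px[pid] + rad * sin(ang), 6), n - 5))
  }
  hasPlaques <- nrow(plaqueTable) > 0
  pMig <- if (hasPlaques) min(0.85, migrationCoeff * areaFraction) else 0
  migrated <- if (nBg > 0) runif(nBg) < pMig else logical(0)
  draws <- c(lapply(seq_len(nBg), function(i)
               if (migrated[i]) drawPa else drawBg),
             rep(list(drawPa), nPa))
  for (draw in draws) {
    for (try in seq_len(maxTries)) {
      p <- draw()
      if (admissible(p) || try == maxTries) {
        centers <- rbind(centers, p)
        break
      }
    }
  }
  unname(centers)
}

renderDiskLabel <- function(labels, cx, cy, radiusPx, id) {
  nx <- nrow(labels); ny <- ncol(labels)
  x0 <- max(1L, floor(cx - radiusPx)); x1 <- min(nx, ceiling(cx + radiusPx))
  y0 <- max(1L, floor(cy - radiusPx)); y1 <- min(ny, ceiling(cy + radiusPx))
  if (x0 > x1 || y0 > y1) return(labels)
  xs <- x0:x1; ys <- y0:y1
  sel <- outer((xs - cx)^2, (ys - cy)^2, "+") <= radiusPx^2
  patch <- labels[xs, ys, drop = FALSE]
  patch[sel & patch == 0L] <- id
  labels[xs, ys] <- patch
  labels
}
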