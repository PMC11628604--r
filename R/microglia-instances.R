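# Microglia instance segmentation: soma detection, body/process split,
# process-mask closing, weighted fusion of exact Euclidean distance
# transforms, and a seeded watershed on the negated fused map.

#' Detect microglial somata and their centroids
#'
#' Classical blob detection standing in for a fine-tuned cell-body model:
#' Gaussian smoothing at a quarter of the minimum soma diameter, Otsu
#' threshold, area filter, intensity-weighted centroids. Externally supplied
#' centroids (e.g. from a dedicated soma segmenter) are accepted verbatim via
#' `centroids`.
#'
#' @param channel microglia intensity matrix.
#' @param pixelSizeUm calibration.
#' @param minSomaDiameterUm minimum soma diameter retained (default 6 um).
#' @param centroids optional 2-column (x, y) pixel matrix/data.frame of
#'   external centroids, returned unchanged with an all-TRUE mask support.
#' @return `list(mask = <logical soma mask>, centroids = <n x 2 matrix, px>)`.
#' @export
detectSomata <- function(channel, pixelSizeUm, minSomaDiameterUm = 6,
                         centroids = NULL) {
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)[, 1:2, drop = FALSE]
    colnames(centroids) <- c("x", "y")
    return(list(mask = matrix(TRUE, nrow(channel), ncol(channel)),
                centroids = centroids))
  }
  stopifnot(is.matrix(channel))
  sigmaPx <- (minSomaDiameterUm / pixelSizeUm) / 4
  sm <- gaussBlur(channel, sigmaPx)
  rng <- range(sm)
  empty <- list(mask = matrix(FALSE, nrow(channel), ncol(channel)),
                centroids = matrix(numeric(), 0, 2,
                                   dimnames = list(NULL, c("x", "y"))))
  if (diff(rng) < .Machine$double.eps) return(empty)
  thr <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)), range = c(0, 1))
  mask <- (sm - rng[1]) / diff(rng) > thr
  # strip thin processes: opening at roughly half the minimum soma radius
  rOpen <- max(1L, floor(minSomaDiameterUm / 4 / pixelSizeUm))
  mask <- EBImage::imageData(EBImage::opening(EBImage::Image(mask * 1),
                                              diskBrush(rOpen))) > 0
  minAreaPx <- pi * (minSomaDiameterUm / 2 / pixelSizeUm)^2 / 2
  lab <- labelComponents(mask, 8L)
  if (max(lab) == 0L) return(empty)
  cents <- list()
  keepMask <- matrix(FALSE, nrow(channel), ncol(channel))
  for (idx in componentIndices(lab)) {
    if (nrow(idx) < minAreaPx) next
    w <- sm[idx]
    cents[[length(cents) + 1L]] <- c(sum(idx[, 1] * w) / sum(w),
                                     sum(idx[, 2] * w) / sum(w))
    keepMask[idx] <- TRUE
  }
  if (!length(cents)) return(empty)
  list(mask = keepMask,
       centroids = matrix(unlist(cents), ncol = 2, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y"))))
}

#' Split a semantic mask into cell bodies and processes
#'
#' Body pixels are those whose Euclidean distance to background is at least
#' `bodyRadiusUm`; everything else in the mask is process. The two masks are
#' disjoint and their union is the input mask.
#'
#' @param mask logical semantic mask.
#' @param cfg a [FusionConfig-class].
#' @param pixelSizeUm calibration.
#' @return `list(body =, process =)` logical matrices.
#' @export
splitBodyProcess <- function(mask, cfg, pixelSizeUm) {
  stopifnot(is(cfg, "FusionConfig"))
  mask <- mask > 0
  edt <- distanceInMask(mask) * pixelSizeUm
  body <- edt >= cfg@bodyRadiusUm
  list(body = body, process = mask & !body)
}

#' Close small gaps in the process mask
#'
#' Morphological closing with a disk of `closingRadiusPx`, repairing small
#' continuity errors that would otherwise break processes into fragments.
#'
#' @param processMask logical matrix.
#' @param cfg a [FusionConfig-class].
#' @return closed logical matrix.
#' @export
closeProcesses <- function(processMask, cfg) {
  stopifnot(is(cfg, "FusionConfig"))
  if (cfg@closingRadiusPx == 0 || !any(processMask)) return(processMask > 0)
  EBImage::imageData(EBImage::closing(
    EBImage::Image((processMask > 0) * 1),
    diskBrush(cfg@closingRadiusPx))) > 0
}

#' Fuse the full-mask and soma distance transforms
#'
#' `fused = wProc * EDT(fullMask) + wSoma * EDT(somaMask)`, zero outside the
#' full mask. The soma mask is intersected with the full mask first. Soma
#' regions therefore dominate the elevation, as required for seeding.
#'
#' @param fullMask logical semantic mask (bodies + processes).
#' @param somaMask logical soma mask.
#' @param cfg a [FusionConfig-class].
#' @return numeric elevation matrix (px-distance units).
#' @export
fuseDistance <- function(fullMask, somaMask, cfg) {
  stopifnot(is(cfg, "FusionConfig"))
  validObject(cfg)
  fullMask <- fullMask > 0
  somaMask <- (somaMask > 0) & fullMask
  fused <- cfg@wProc * distanceInMask(fullMask) +
    cfg@wSoma * distanceInMask(somaMask)
  fused[!fullMask] <- 0
  fused
}

#' Seeded watershed on the negated fused elevation map
#'
#' Priority flooding restricted to the mask, with the seed centroids as the
#' flooding minima of the negated map (distance peaks become basins). Every
#' mask pixel receives exactly one label; ties are broken by (elevation,
#' linear pixel index) so the result is deterministic. Seeds falling outside
#' the mask are dropped with a warning.
#'
#' @param fused elevation map from [fuseDistance()].
#' @param seeds n x 2 matrix of (x, y) seed centroids in pixels.
#' @param fullMask logical semantic mask.
#' @return integer label matrix (0 background, 1..K = cells in seed order).
#' @export
watershedInstances <- function(fused, seeds, fullMask) {
  fullMask <- fullMask > 0
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) {
    if (any(fullMask)) stop("no seeds supplied for a non-empty mask")
    return(matrix(0L, nrow(fullMask), ncol(fullMask)))
  }
  sx <- as.integer(round(seeds[, 1])); sy <- as.integer(round(seeds[, 2]))
  inside <- sx >= 1L & sx <= nrow(fullMask) & sy >= 1L & sy <= ncol(fullMask)
  inside[inside] <- fullMask[cbind(sx[inside], sy[inside])]
  if (!all(inside))
    warning(sum(!inside), " seed(s) outside the mask were dropped")
  if (!any(inside)) {
    if (any(fullMask)) stop("all seeds fall outside the mask")
    return(matrix(0L, nrow(fullMask), ncol(fullMask)))
  }
  seedMat <- cbind(sx[inside], sy[inside], seq_len(sum(inside)))
  lab <- .watershedFlood(-fused, fullMask, seedMat)
  orphan <- fullMask & lab == 0L
  if (any(orphan)) {
    # unseeded components take the label of the nearest labelled pixel
    labbed <- which(lab > 0L, arr.ind = TRUE)
    for (idx in componentIndices(labelComponents(orphan, 8L))) {
      cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
      j <- which.min((labbed[, 1] - cx)^2 + (labbed[, 2] - cy)^2)
      lab[idx] <- lab[labbed[j, 1], labbed[j, 2]]
    }
  }
  lab
}

#' Full microglia instance-segmentation pipeline for one field
#'
#' Runs soma detection, body/process split, closing, distance fusion and the
#' seeded watershed.
#'
#' @param channel microglia intensity matrix.
#' @param mask logical semantic mask of all microglial pixels.
#' @param pixelSizeUm calibration.
#' @param cfg a [FusionConfig-class].
#' @param centroids optional external soma centroids (n x 2, px).
#' @return `list(labels = <label matrix>, centroids =, body =, process =)`.
#' @export
segmentMicroglia <- function(channel, mask, pixelSizeUm, cfg = fusionConfig(),
                             centroids = NULL) {
  somata <- detectSomata(channel, pixelSizeUm, centroids = centroids)
  sp <- splitBodyProcess(mask, cfg, pixelSizeUm)
  proc <- closeProcesses(sp$process, cfg)
  full <- (mask > 0) | proc
  # with external centroids there is no soma segmentation; the EDT-thickness
  # body mask is the soma-area stand-in for the weighted fusion
  somaMask <- if (is.null(centroids)) somata$mask & full else sp$body
  fused <- fuseDistance(full, somaMask, cfg)
  labels <- watershedInstances(fused, somata$centroids, full)
  list(labels = labels, centroids = somata$centroids,
       body = sp$body, process = proc)
}
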