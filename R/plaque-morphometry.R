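# Plaque instance segmentation and per-plaque morphometry: size, location,
# grey-level co-occurrence texture and the Angular Second Moment (ASM), the
# compactness estimate (higher = more homogeneous plaque).

sizeClassOf <- function(diameterUm) {
  cut(diameterUm, breaks = c(-Inf, 20, 40, Inf),
      labels = c("small", "medium", "large"), right = TRUE)
}

#' Segment individual plaques from a semantic mask
#'
#' 8-connected components of the binary mask; components below the minimum
#' equivalent diameter (default ~4 um) are discarded. ASM is left `NA` here
#' and filled by [computeAsm()] via [plaqueAsm()].
#'
#' @param mask logical/binary matrix.
#' @param pixelSizeUm calibration.
#' @param minDiameterUm minimum equivalent diameter retained (default 4 um).
#' @return `list(labels = <integer label matrix>, records = <data.frame>)`
#'   with per-plaque `plaque_id, cx_um, cy_um, area_um2,
#'   equivalent_diameter_um, asm, size_class, border_touching`.
#' @examples
#' m <- matrix(FALSE, 64, 64); m[20:40, 20:40] <- TRUE
#' segmentPlaques(m, pixelSizeUm = 1)$records$size_class
#' @export
segmentPlaques <- function(mask, pixelSizeUm, minDiameterUm = 4) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  lab <- labelComponents(mask, 8L)
  k <- max(lab)
  if (k == 0L) return(list(labels = lab, records = emptyPlaqueRecords()))
  recs <- vector("list", k)
  keep <- 0L
  out <- matrix(0L, nrow(mask), ncol(mask))
  compIdx <- componentIndices(lab)
  for (i in seq_len(k)) {
    idx <- compIdx[[i]]
    areaUm2 <- nrow(idx) * pixelSizeUm^2
    eqd <- 2 * sqrt(areaUm2 / pi)
    if (eqd < minDiameterUm) next
    keep <- keep + 1L
    out[idx] <- keep
    border <- any(idx[, 1] %in% c(1L, nrow(mask))) ||
      any(idx[, 2] %in% c(1L, ncol(mask)))
    recs[[keep]] <- data.frame(
      plaque_id = keep,
      cx_um = (mean(idx[, 1]) - 0.5) * pixelSizeUm,
      cy_um = (mean(idx[, 2]) - 0.5) * pixelSizeUm,
      area_um2 = areaUm2,
      equivalent_diameter_um = eqd,
      asm = NA_real_,
      size_class = sizeClassOf(eqd),
      border_touching = border
    )
  }
  records <- if (keep > 0L) do.call(rbind, recs[seq_len(keep)]) else emptyPlaqueRecords()
  list(labels = out, records = records)
}

emptyPlaqueRecords <- function() {
  data.frame(plaque_id = integer(), cx_um = numeric(), cy_um = numeric(),
             area_um2 = numeric(), equivalent_diameter_um = numeric(),
             asm = numeric(),
             size_class = factor(character(), levels = c("small", "medium", "large")),
             border_touching = logical())
}

glcmOffsets <- list(
  "0"   = c(1L, 0L),
  "45"  = c(1L, 1L),
  "90"  = c(0L, 1L),
  "135" = c(-1L, 1L)
)

quantizeInstance <- function(channel, mask, levels) {
  v <- channel[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(channel), ncol(channel))
  if (diff(rng) < .Machine$double.eps) {
    q[mask] <- 1L
  } else {
    b <- floor((v - rng[1]) / diff(rng) * levels) + 1L
    q[mask] <- pmin(b, levels)
  }
  q
}

#' Grey-level co-occurrence matrices of one plaque instance
#'
#' Intensities inside the instance are min-max quantized to `levels` grey
#' bins; for each offset (four angles at distance 1), only pixel pairs with
#' both members inside the instance are counted. Each returned matrix is
#' symmetric and sums to 1. Angles with no valid pair are dropped.
#'
#' @param channel intensity matrix (raw channel).
#' @param mask logical instance mask (>= 2 pixels).
#' @param levels number of grey levels (default 64).
#' @return named list (by angle, degrees) of `levels x levels` matrices.
#' @examples
#' patch <- rbind(c(0, 0), c(1, 1))   # indexed [x, y]
#' g <- computeGlcm(patch, matrix(TRUE, 2, 2), levels = 2)
#' g[["90"]]  # pairs along y: p(1,1) = p(2,2) = 0.5 on the diagonal
#' @export
computeGlcm <- function(channel, mask, levels = 64L) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(mask)))
  mask <- mask > 0
  if (sum(mask) < 2L) stop("instance must contain at least 2 pixels")
  q <- quantizeInstance(channel, mask, levels)
  nx <- nrow(channel); ny <- ncol(channel)
  out <- list()
  for (ang in names(glcmOffsets)) {
    o <- glcmOffsets[[ang]]
    xs <- seq_len(nx); ys <- seq_len(ny)
    vx <- xs[xs + o[1] >= 1L & xs + o[1] <= nx]
    vy <- ys[ys + o[2] >= 1L & ys + o[2] <= ny]
    if (!length(vx) || !length(vy)) next
    a <- q[vx, vy, drop = FALSE]
    b <- q[vx + o[1], vy + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ii <- a[ok]; jj <- b[ok]
    cm <- matrix(0, levels, levels)
    tab <- tabulate((jj - 1L) * levels + ii, nbins = levels * levels)
    cm[] <- tab
    cm <- cm + t(cm)
    out[[ang]] <- cm / sum(cm)
  }
  out
}

#' Angular Second Moment from co-occurrence matrices
#'
#' `ASM_theta = sum_ij p_theta(i,j)^2`, averaged over the defined angles
#' (rotation invariance at the feature level). A constant patch gives 1; an
#' ideal two-level checkerboard gives 0.5.
#'
#' @param glcms list from [computeGlcm()].
#' @return ASM in (0, 1]; `NA` (with a warning) when no angle is defined.
#' @export
computeAsm <- function(glcms) {
  if (length(glcms) == 0L) {
    warning("no defined co-occurrence angle; ASM is NA")
    return(NA_real_)
  }
  mean(vapply(glcms, function(p) sum(p^2), numeric(1)))
}

#' Per-plaque ASM over an instance label image
#'
#' @param channel raw intensity matrix.
#' @param labels instance label matrix from [segmentPlaques()].
#' @param records the matching records data.frame; its `asm` column is filled.
#' @param levels grey levels (default 64).
#' @return `records` with `asm` populated.
#' @export
plaqueAsm <- function(channel, labels, records, levels = 64L) {
  for (i in seq_len(nrow(records))) {
    m <- labels == records$plaque_id[i]
    records$asm[i] <- if (sum(m) >= 2L) computeAsm(computeGlcm(channel, m, levels))
                      else NA_real_
  }
  records
}

#' Summarize the plaques of one field of view
#'
#' @param records per-plaque data.frame from [segmentPlaques()].
#' @param fovAreaUm2 physical field area (um^2); pass `fovSize(fov)^2`.
#' @return one-row data.frame: `n_plaques, area_fraction`, per-class counts
#'   `n_small, n_medium, n_large` and proportions.
#' @export
summarizeFovPlaques <- function(records, fovAreaUm2) {
  n <- nrow(records)
  counts <- table(factor(records$size_class, levels = c("small", "medium", "large")))
  data.frame(
    n_plaques = n,
    area_fraction = sum(records$area_um2) / fovAreaUm2,
    n_small = as.integer(counts[["small"]]),
    n_medium = as.integer(counts[["medium"]]),
    n_large = as.integer(counts[["large"]]),
    prop_small = if (n > 0) counts[["small"]] / n else 0,
    prop_medium = if (n > 0) counts[["medium"]] / n else 0,
    prop_large = if (n > 0) counts[["large"]] / n else 0
  )
}
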