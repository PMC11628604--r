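# Per-cell microglia morphometrics and the plaque-association rule.

shiftMat <- function(m, dx, dy) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(FALSE, n1, n2)
  xs <- seq_len(n1) - dx; ys <- seq_len(n2) - dy
  okx <- xs >= 1 & xs <= n1; oky <- ys >= 1 & ys <= n2
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iterative two-subcycle thinning of a binary mask down to an 8-connected,
#' one-pixel-wide skeleton.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  img <- mask > 0
  if (!any(img)) return(img)
  # neighbours P2..P9 clockwise from north; matrix convention [x, y]
  offs <- list(c(0, -1), c(1, -1), c(1, 0), c(1, 1),
               c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shiftMat(img, o[1], o[2]))
      B <- Reduce(`+`, nb)
      seq9 <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(i) (!seq9[[i]]) & seq9[[i + 1]]))
      if (step == 1) {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      if (any(cond)) { img <- img & !cond; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# Summed skeleton path length in px: orthogonal neighbours contribute 1,
# diagonal neighbours sqrt(2), a diagonal being skipped when either of its
# two rectifying orthogonal pixels is present (the path runs through them).
skeletonLengthPx <- function(skel) {
  if (!any(skel)) return(0)
  e <- shiftMat(skel, -1, 0)   # east neighbour present at p
  s <- shiftMat(skel, 0, -1)
  se <- shiftMat(skel, -1, -1)
  ne <- shiftMat(skel, -1, 1)
  n <- shiftMat(skel, 0, 1)
  orth <- sum(skel & e) + sum(skel & s)
  diagSE <- skel & se & !(e | s)
  diagNE <- skel & ne & !(e | n)
  orth + sqrt(2) * (sum(diagSE) + sum(diagNE))
}

#' Convex territory area of one cell instance
#'
#' Area of the convex hull of the instance's pixel centers, scaled to um^2.
#' Fewer than 3 non-collinear pixels give area 0.
#'
#' @param pixels n x 2 matrix of pixel coordinates (or a logical mask).
#' @param pixelSizeUm calibration.
#' @return convex area in um^2.
#' @examples
#' measureTerritory(matrix(TRUE, 11, 11), pixelSizeUm = 1) # 100
#' @export
measureTerritory <- function(pixels, pixelSizeUm) {
  if (is.matrix(pixels) && (is.logical(pixels) || all(pixels %in% c(0, 1))) &&
      ncol(pixels) != 2)
    pixels <- which(pixels > 0, arr.ind = TRUE)
  if (is.logical(pixels)) pixels <- which(pixels, arr.ind = TRUE)
  pixels <- unique(as.matrix(pixels)[, 1:2, drop = FALSE])
  if (nrow(pixels) < 3L) return(0)
  h <- grDevices::chull(pixels)
  hp <- pixels[h, , drop = FALSE]
  if (nrow(hp) < 3L) return(0)
  x <- hp[, 1]; y <- hp[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  area * pixelSizeUm^2
}

#' Total process length of one cell
#'
#' Skeletonizes the instance minus its body mask and sums 8-connected skeleton
#' steps (orthogonal 1 px, diagonal sqrt(2) px).
#'
#' @param instanceMask logical mask of the whole cell.
#' @param bodyMask logical mask of the cell body (may be empty).
#' @param pixelSizeUm calibration.
#' @return process length in um (0 when there are no process pixels).
#' @export
measureProcessLength <- function(instanceMask, bodyMask, pixelSizeUm) {
  proc <- (instanceMask > 0) & !(bodyMask > 0)
  if (!any(proc)) return(0)
  skeletonLengthPx(skeletonize(proc)) * pixelSizeUm
}

#' Mean distance to the three nearest neighbouring centroids
#'
#' @param centroids n x 2 matrix in um (or px times `scale`).
#' @param scale multiplier applied to coordinates (default 1).
#' @return numeric vector of per-cell mean 3-NN distances; all `NA` (with a
#'   warning) when fewer than 4 centroids are supplied.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
#' nn3Distance(sq)  # (10 + 10 + 10 * sqrt(2)) / 3 each
#' @export
nn3Distance <- function(centroids, scale = 1) {
  centroids <- as.matrix(centroids) * scale
  n <- nrow(centroids)
  if (n < 4L) {
    warning("fewer than 4 centroids: 3-NN distance undefined")
    return(rep(NA_real_, n))
  }
  d <- as.matrix(dist(centroids))
  vapply(seq_len(n), function(i) mean(sort(d[i, -i])[1:3]), numeric(1))
}

#' Classify microglia as plaque-associated by the 5 um rule
#'
#' A cell is plaque-associated when its centroid lies inside the thresholded
#' plaque mask or within `thresholdUm` of a plaque edge. Distances are exact
#' Euclidean distances between pixel centers (EDT of the mask complement);
#' the signed distance is negative inside plaques.
#'
#' @param centroids n x 2 (x, y) matrix in pixels.
#' @param plaqueMask logical plaque mask.
#' @param pixelSizeUm calibration.
#' @param thresholdUm association distance (default 5 um).
#' @return data.frame `association` (factor `plaque_associated` /
#'   `non_plaque_associated`) and `dist_to_plaque_edge_um` (signed).
#' @export
classifyAssociation <- function(centroids, plaqueMask, pixelSizeUm,
                                thresholdUm = 5) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  lv <- c("plaque_associated", "non_plaque_associated")
  if (n == 0L)
    return(data.frame(association = factor(character(), levels = lv),
                      dist_to_plaque_edge_um = numeric()))
  plaqueMask <- plaqueMask > 0
  px <- pmin(pmax(as.integer(round(centroids[, 1])), 1L), nrow(plaqueMask))
  py <- pmin(pmax(as.integer(round(centroids[, 2])), 1L), ncol(plaqueMask))
  idx <- cbind(px, py)
  if (!any(plaqueMask)) {
    return(data.frame(association = factor(rep("non_plaque_associated", n), levels = lv),
                      dist_to_plaque_edge_um = rep(Inf, n)))
  }
  dOut <- distanceToMask(plaqueMask) * pixelSizeUm   # 0 on the mask
  dIn <- distanceInMask(plaqueMask) * pixelSizeUm    # 0 off the mask
  inside <- plaqueMask[idx]
  signed <- ifelse(inside, -dIn[idx], dOut[idx])
  pa <- inside | (dOut[idx] <= thresholdUm)
  data.frame(
    association = factor(ifelse(pa, "plaque_associated", "non_plaque_associated"),
                         levels = lv),
    dist_to_plaque_edge_um = signed
  )
}

#' Per-cell morphometrics for a labelled microglia field
#'
#' @param labels instance label matrix from [watershedInstances()].
#' @param bodyMask logical body mask from [splitBodyProcess()].
#' @param plaqueMask logical plaque mask (may be empty).
#' @param pixelSizeUm calibration.
#' @param thresholdUm association distance (default 5 um).
#' @param centroids optional n x 2 px matrix overriding the label centroids
#'   (row k used for cell k).
#' @return data.frame of per-cell records: `cell_id, cx_um, cy_um,
#'   convex_area_um2, process_length_um, nn3_mean_dist_um, association,
#'   dist_to_plaque_edge_um, border_touching`.
#' @export
measureMicroglia <- function(labels, bodyMask, plaqueMask, pixelSizeUm,
                             thresholdUm = 5, centroids = NULL) {
  k <- max(labels)
  if (k == 0L)
    return(data.frame(cell_id = integer(), cx_um = numeric(), cy_um = numeric(),
                      convex_area_um2 = numeric(), process_length_um = numeric(),
                      nn3_mean_dist_um = numeric(),
                      association = factor(character(),
                        levels = c("plaque_associated", "non_plaque_associated")),
                      dist_to_plaque_edge_um = numeric(),
                      border_touching = logical()))
  cents <- matrix(NA_real_, k, 2)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- which(labels == i, arr.ind = TRUE)
    cents[i, ] <- if (!is.null(centroids) && nrow(centroids) >= i)
      as.numeric(centroids[i, 1:2]) else colMeans(idx)
    inst <- labels == i
    rows[[i]] <- data.frame(
      cell_id = i,
      cx_um = (cents[i, 1] - 0.5) * pixelSizeUm,
      cy_um = (cents[i, 2] - 0.5) * pixelSizeUm,
      convex_area_um2 = measureTerritory(idx, pixelSizeUm),
      process_length_um = measureProcessLength(inst, inst & bodyMask, pixelSizeUm),
      border_touching = any(idx[, 1] %in% c(1L, nrow(labels))) ||
        any(idx[, 2] %in% c(1L, ncol(labels)))
    )
  }
  rec <- do.call(rbind, rows)
  rec$nn3_mean_dist_um <- if (k >= 4L) nn3Distance(cents, scale = pixelSizeUm)
                          else rep(NA_real_, k)
  assoc <- classifyAssociation(cents, plaqueMask, pixelSizeUm, thresholdUm)
  rec$association <- assoc$association
  rec$dist_to_plaque_edge_um <- assoc$dist_to_plaque_edge_um
  rec[, c("cell_id", "cx_um", "cy_um", "convex_area_um2", "process_length_um",
          "nn3_mean_dist_um", "association", "dist_to_plaque_edge_um",
          "border_touching")]
}

#' Summarize microglia of one field of view
#'
#' @param records per-cell data.frame from [measureMicroglia()].
#' @param plaqueSummary one-row data.frame from [summarizeFovPlaques()] whose
#'   `area_fraction` is joined for the regression stage (optional).
#' @return one-row data.frame: `n_total, n_plaque_associated,
#'   n_non_plaque_associated, plaque_area_fraction`.
#' @export
summarizeFovMicroglia <- function(records, plaqueSummary = NULL) {
  nPa <- sum(records$association == "plaque_associated")
  data.frame(
    n_total = nrow(records),
    n_plaque_associated = nPa,
    n_non_plaque_associated = nrow(records) - nPa,
    plaque_area_fraction = if (!is.null(plaqueSummary))
      plaqueSummary$area_fraction else NA_real_
  )
}
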