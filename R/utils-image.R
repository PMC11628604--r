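# Internal image helpers. All filters use mirror (symmetric) boundary
# handling: images are padded by reflection, filtered, then cropped, so that
# scales larger than the frame remain well defined.

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Reflected (symmetric, edge-repeated) index into 1..n for arbitrary i.
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  k <- (i - 1L) %% (2L * n)
  ifelse(k < n, k + 1L, 2L * n - k)
}

padMirror <- function(x, p) {
  if (p <= 0) return(x)
  ri <- reflectIndex(seq(1L - p, nrow(x) + p), nrow(x))
  ci <- reflectIndex(seq(1L - p, ncol(x) + p), ncol(x))
  x[ri, ci, drop = FALSE]
}

cropPad <- function(x, p, nx, ny) x[p + seq_len(nx), p + seq_len(ny), drop = FALSE]

gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur with mirror boundary (FFT convolution on the padded image).
gaussBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussKernel1d(sigma)
  p <- (length(k) - 1L) %/% 2L
  xp <- padMirror(x, p)
  out <- EBImage::imageData(EBImage::filter2(EBImage::Image(xp), outer(k, k),
                                             boundary = "circular"))
  cropPad(out, p, nrow(x), ncol(x))
}

# Per-component pixel indices (arr.ind) of a label matrix, one scan.
componentIndices <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(list())
  sp <- split(pos, lab[pos])
  nx <- nrow(lab)
  lapply(sp, function(p) cbind((p - 1L) %% nx + 1L, (p - 1L) %/% nx + 1L))
}

# Central-difference first derivatives of a (pre-smoothed) image.
imageGradient <- function(x) {
  xp <- padMirror(x, 1L)
  n1 <- nrow(x); n2 <- ncol(x)
  gx <- (xp[3:(n1 + 2), 2:(n2 + 1)] - xp[1:n1, 2:(n2 + 1)]) / 2
  gy <- (xp[2:(n1 + 1), 3:(n2 + 2)] - xp[2:(n1 + 1), 1:n2]) / 2
  list(gx = gx, gy = gy)
}

# Second derivatives (Hessian entries) of a (pre-smoothed) image.
imageHessian <- function(x) {
  xp <- padMirror(x, 1L)
  n1 <- nrow(x); n2 <- ncol(x)
  c0 <- xp[2:(n1 + 1), 2:(n2 + 1)]
  dxx <- xp[3:(n1 + 2), 2:(n2 + 1)] - 2 * c0 + xp[1:n1, 2:(n2 + 1)]
  dyy <- xp[2:(n1 + 1), 3:(n2 + 2)] - 2 * c0 + xp[2:(n1 + 1), 1:n2]
  dxy <- (xp[3:(n1 + 2), 3:(n2 + 2)] - xp[3:(n1 + 2), 1:n2] -
          xp[1:n1, 3:(n2 + 2)] + xp[1:n1, 1:n2]) / 4
  list(dxx = dxx, dyy = dyy, dxy = dxy)
}

# Running box mean / max over a (2w+1) square window, mirror boundary.
boxFilter <- function(x, w, fun = c("mean", "max")) {
  fun <- match.arg(fun)
  w <- as.integer(round(w))
  if (w <= 0) return(x)
  xp <- padMirror(x, w)
  if (fun == "mean") {
    k <- matrix(1 / (2 * w + 1)^2, 2 * w + 1, 2 * w + 1)
    out <- EBImage::filter2(EBImage::Image(xp), k, boundary = "replicate")
    out <- EBImage::imageData(out)
  } else {
    out <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(xp), EBImage::makeBrush(2 * w + 1, "box")))
  }
  cropPad(out, w, nrow(x), ncol(x))
}

diskBrush <- function(radiusPx) {
  s <- 2L * as.integer(ceiling(radiusPx)) + 1L
  if (s < 3L) s <- 3L
  EBImage::makeBrush(s, shape = "disc")
}

# Coordinate grids (pixel centers at integers, matrix indexed [x, y]).
pixelGrid <- function(nx, ny) {
  list(x = matrix(seq_len(nx), nx, ny),
       y = matrix(seq_len(ny), nx, ny, byrow = TRUE))
}

# Exact Euclidean distance (px) of every pixel to the nearest TRUE pixel of
# `mask`; 0 on the mask itself. Built on EBImage's exact distmap.
distanceToMask <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  EBImage::imageData(EBImage::distmap(EBImage::Image(1 - mask * 1)))
}

# EDT within the mask: distance to nearest background pixel, 0 outside.
distanceInMask <- function(mask) {
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  if (all(mask)) {
    # no background: distance to frame edge
    g <- pixelGrid(nrow(mask), ncol(mask))
    return(pmin(g$x, nrow(mask) + 1 - g$x, g$y, ncol(mask) + 1 - g$y))
  }
  EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
}

labelComponents <- function(mask, connectivity = 8L) {
  # EBImage::bwlabel is 4-connected; for 8-connectivity, merge 4-connected
  # labels that touch diagonally via union-find.
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (connectivity == 8L) {
    n1 <- nrow(lab); n2 <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-n1, -n2]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-1, -n2]), as.vector(lab[-n1, -1]))
    )
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0] <- roots[lab[lab > 0]]
    }
  }
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}
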