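#' Generate a synthetic SiMPull TIRF frame with ground-truth spot positions
#'
#' Renders `K ~ Poisson(spotRate)` diffraction-limited Gaussian spots at
#' recorded continuous positions over a noisy background. Spot amplitude is
#' `snr * noiseSd` so the signal-to-noise ratio is directly configurable.
#'
#' @param spec a [GroupSpec-class] (only `spotRate` is used).
#' @param seed integer seed.
#' @param framePx square frame side in pixels (default 256).
#' @param spotSigmaPx Gaussian spot width (default 1.5 px).
#' @param snr spot peak amplitude over noise SD (default 10).
#' @param background constant background level.
#' @param noiseSd additive Gaussian noise SD.
#' @return `list(fov = FieldOfView, truth = GroundTruth)`; spot centres are in
#'   the `spotPositions` slot.
#' @examples
#' g <- generateSimpullFov(groupSpec("APOEKO", spotRate = 20), seed = 7)
#' nrow(g$truth@spotPositions)
#' @export
generateSimpullFov <- function(spec, seed, framePx = 256L, spotSigmaPx = 1.5,
                               snr = 10, background = 0.1, noiseSd = 0.02) {
  stopifnot(is(spec, "GroupSpec"))
  if (spec@spotRate < 0) stop("spotRate must be >= 0")
  n <- as.integer(framePx)
  withSeed(seed, {
    k <- rpois(1L, spec@spotRate)
    frame <- matrix(background, n, n)
    pos <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("x", "y")))
    if (k > 0) {
      margin <- 4
      pos <- cbind(x = runif(k, margin, n - margin),
                   y = runif(k, margin, n - margin))
      amp <- snr * noiseSd
      r <- ceiling(4 * spotSigmaPx)
      for (i in seq_len(k)) {
        xs <- max(1L, floor(pos[i, 1] - r)):min(n, ceiling(pos[i, 1] + r))
        ys <- max(1L, floor(pos[i, 2] - r)):min(n, ceiling(pos[i, 2] + r))
        g <- exp(-outer((xs - pos[i, 1])^2, (ys - pos[i, 2])^2, "+") /
                   (2 * spotSigmaPx^2))
        frame[xs, ys] <- frame[xs, ys] + amp * g
      }
    }
    frame <- frame + matrix(rnorm(n * n, 0, noiseSd), n, n)
    truth <- emptyGroundTruth(0L, 0L)
    truth@spotPositions <- pos
    fov <- FieldOfView(list(spots = frame), pixelSizeUm = 0.1)
    list(fov = fov, truth = truth)
  })
}
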