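# Diffraction-limited spot counting for SiMPull TIRF frames. One shared
# configuration (size and brightness thresholds) is applied to every frame.

#' Detect diffraction-limited spots in a TIRF frame
#'
#' Difference-of-gaussians band-pass, robust brightness threshold at
#' `median + k * MAD` of the filtered frame (MAD floored at machine epsilon
#' so constant frames yield zero spots), 8-connected components, local-maxima
#' deduplication at the minimum separation, and the shared size window.
#' Components inside the area window are split by their validated regional
#' maxima, so a pair of touching spots merged into one component yields two
#' detections, while an oversized component (a saturated blob or its edge
#' ring) yields none.
#'
#' @param frame numeric matrix (single channel).
#' @param cfg a [SpotDetectionConfig-class].
#' @return `list(n_spots = <int>, centroids = <n x 2 (x, y) px matrix>)`.
#' @examples
#' g <- generateSimpullFov(groupSpec("APOE2", spotRate = 30), seed = 3)
#' detectSpots(getChannel(g$fov, "spots"), spotConfig())$n_spots
#' @export
detectSpots <- function(frame, cfg = spotConfig()) {
  stopifnot(is.matrix(frame), is(cfg, "SpotDetectionConfig"))
  validObject(cfg)
  dog <- gaussBlur(frame, cfg@dogSigmaPx) - gaussBlur(frame, 1.6 * cfg@dogSigmaPx)
  madDog <- max(mad(dog), .Machine$double.eps)
  thr <- median(dog) + cfg@brightnessK * madDog
  # two-stage detect-then-validate: the component mask forms at k MADs, and a
  # candidate spot's peak must clear one further MAD unit, which suppresses
  # near-threshold noise clusters while leaving diffraction-limited spots
  # (peaks many MADs above threshold) untouched
  peakThr <- median(dog) + (cfg@brightnessK + 1) * madDog
  mask <- dog > thr
  none <- list(n_spots = 0L,
               centroids = matrix(numeric(), 0, 2,
                                  dimnames = list(NULL, c("x", "y"))))
  if (!any(mask)) return(none)
  lab <- labelComponents(mask, 8L)
  # regional maxima of the filtered frame within the mask (3 x 3 plateaus)
  locmax <- mask & (dog >= boxFilter(dog, 1, "max") - .Machine$double.eps)
  cents <- list()
  for (idx in componentIndices(lab)) {
    a <- nrow(idx)
    if (a < cfg@minAreaPx || a > cfg@maxAreaPx) next
    mx <- idx[locmax[idx] & dog[idx] > peakThr, , drop = FALSE]
    if (nrow(mx) == 0L) next
    # deduplicate maxima closer than the minimum separation (brightest first)
    ord <- order(dog[mx], decreasing = TRUE)
    kept <- integer()
    for (j in ord) {
      if (!length(kept) ||
          all((mx[kept, 1] - mx[j, 1])^2 + (mx[kept, 2] - mx[j, 2])^2 >=
              cfg@minSeparationPx^2))
        kept <- c(kept, j)
    }
    for (j in sort(kept)) {
      # sub-pixel position: filtered-intensity centroid of the 3 x 3 window
      xs <- max(1L, mx[j, 1] - 1L):min(nrow(dog), mx[j, 1] + 1L)
      ys <- max(1L, mx[j, 2] - 1L):min(ncol(dog), mx[j, 2] + 1L)
      w <- dog[xs, ys, drop = FALSE]
      w <- w - min(w) + .Machine$double.eps
      cents[[length(cents) + 1L]] <- c(sum(outer(xs, ys, function(x, y) x) * w) / sum(w),
                                       sum(outer(xs, ys, function(x, y) y) * w) / sum(w))
    }
  }
  if (!length(cents)) return(none)
  out <- matrix(unlist(cents), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("x", "y")))
  list(n_spots = nrow(out), centroids = out)
}

#' Aggregate spot counts frames -> replicates -> mice
#'
#' Replicate value = mean over its frames; mouse value = mean over its
#' replicates (mean of means, mirroring acquisition of >= 9 fields per
#' technical replicate and 3 replicates per mouse). Replicates with fewer
#' than `minFrames` frames raise a warning.
#'
#' @param records data.frame with columns `n_spots, replicate_id, mouse_id`.
#' @param minFrames expected frames per replicate (default 9).
#' @return `list(byReplicate =, byMouse =)` data.frames.
#' @examples
#' r <- data.frame(n_spots = c(10, 20, 30), replicate_id = "r1", mouse_id = "m1")
#' suppressWarnings(aggregateCounts(r))$byReplicate$mean_spots # 20
#' @export
aggregateCounts <- function(records, minFrames = 9L) {
  stopifnot(all(c("n_spots", "replicate_id", "mouse_id") %in% names(records)))
  key <- interaction(records$mouse_id, records$replicate_id, drop = TRUE)
  nFrames <- tapply(records$n_spots, key, length)
  if (any(nFrames < minFrames))
    warning(sum(nFrames < minFrames), " replicate(s) have fewer than ",
            minFrames, " frames")
  byRep <- data.frame(
    mouse_id = tapply(as.character(records$mouse_id), key, `[`, 1L),
    replicate_id = tapply(as.character(records$replicate_id), key, `[`, 1L),
    n_frames = as.integer(nFrames),
    mean_spots = as.numeric(tapply(records$n_spots, key, mean))
  )
  rownames(byRep) <- NULL
  byMouse <- data.frame(
    mouse_id = names(tapply(byRep$mean_spots, byRep$mouse_id, mean)),
    mean_spots = as.numeric(tapply(byRep$mean_spots, byRep$mouse_id, mean)),
    n_replicates = as.integer(tapply(byRep$mean_spots, byRep$mouse_id, length))
  )
  rownames(byMouse) <- NULL
  list(byReplicate = byRep, byMouse = byMouse)
}
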