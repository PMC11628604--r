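# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Double-loop co-occurrence oracle: quantize inside the mask on its min-max
# range, count ordered pairs with both pixels inside, symmetrize, normalize.
bruteGlcm <- function(channel, mask, levels = 64L, offset = c(1L, 0L)) {
  v <- channel[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(channel), ncol(channel))
  q[mask] <- if (diff(rng) < .Machine$double.eps) 1L else
    pmin(floor((channel[mask] - rng[1]) / diff(rng) * levels) + 1L, levels)
  cm <- matrix(0, levels, levels)
  for (x in seq_len(nrow(channel))) {
    for (y in seq_len(ncol(channel))) {
      x2 <- x + offset[1]; y2 <- y + offset[2]
      if (x2 < 1 || x2 > nrow(channel) || y2 < 1 || y2 > ncol(channel)) next
      if (is.na(q[x, y]) || is.na(q[x2, y2])) next
      cm[q[x, y], q[x2, y2]] <- cm[q[x, y], q[x2, y2]] + 1
    }
  }
  cm <- cm + t(cm)
  if (sum(cm) == 0) return(NULL)
  cm / sum(cm)
}

# Brute-force plaque-association oracle: minimum distance from each centroid's
# containing pixel center to every mask pixel center.
bruteAssociation <- function(centroids, plaqueMask, pixelSizeUm, thresholdUm) {
  mp <- which(plaqueMask, arr.ind = TRUE)
  vapply(seq_len(nrow(centroids)), function(i) {
    px <- round(centroids[i, 1]); py <- round(centroids[i, 2])
    if (nrow(mp) == 0) return(FALSE)
    if (plaqueMask[px, py]) return(TRUE)
    dmin <- sqrt(min((mp[, 1] - px)^2 + (mp[, 2] - py)^2)) * pixelSizeUm
    dmin <= thresholdUm
  }, logical(1))
}

# Greedy 1:1 matching of truth instances to predicted labels at an IoU floor.
matchInstances <- function(truthLabels, predLabels, nTruth, iouMin = 0.5) {
  matched <- 0L
  used <- integer()
  for (i in seq_len(nTruth)) {
    ti <- truthLabels == i
    if (!any(ti)) next
    cand <- predLabels[ti]
    cand <- cand[cand > 0]
    if (!length(cand)) next
    j <- as.integer(names(which.max(table(cand))))
    if (j %in% used) next
    pj <- predLabels == j
    if (sum(ti & pj) / sum(ti | pj) >= iouMin) {
      matched <- matched + 1L
      used <- c(used, j)
    }
  }
  matched
}

# Recall/precision of detected spot centroids against truth positions.
spotPrecisionRecall <- function(truthPos, detPos, matchRadius = 2) {
  if (nrow(detPos) == 0)
    return(c(recall = if (nrow(truthPos)) 0 else 1, precision = 1))
  used <- rep(FALSE, nrow(detPos))
  tp <- 0L
  for (i in seq_len(nrow(truthPos))) {
    d <- sqrt((detPos[, 1] - truthPos[i, 1])^2 + (detPos[, 2] - truthPos[i, 2])^2)
    j <- which(!used & d <= matchRadius)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(recall = tp / max(nrow(truthPos), 1), precision = tp / nrow(detPos))
}

# Filled disk mask on an n x n frame.
diskMask <- function(n, cx, cy, r) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  matrix((g$x - cx)^2 + (g$y - cy)^2 <= r^2, n, n)
}

# Soma disk mask for a set of ground-truth microglia.
truthSomaMask <- function(truth, pixelSizeUm, dims) {
  soma <- matrix(FALSE, dims[1], dims[2])
  tab <- truth@microgliaTable
  for (i in seq_len(nrow(tab))) {
    r <- tab$soma_radius_um[i] / pixelSizeUm
    xs <- max(1, floor(tab$soma_x_px[i] - r)):min(dims[1], ceiling(tab$soma_x_px[i] + r))
    ys <- max(1, floor(tab$soma_y_px[i] - r)):min(dims[2], ceiling(tab$soma_y_px[i] + r))
    sel <- outer((xs - tab$soma_x_px[i])^2, (ys - tab$soma_y_px[i])^2, "+") <= r^2
    soma[xs, ys][sel] <- TRUE
  }
  soma
}

# Measured Fig-4Dii-style per-mouse table for one rendered cohort.
measureCohort4d <- function(co, pixelSizeUm, thresholdValue = 0.05) {
  rows <- lapply(co$fovs, function(rec) {
    pm <- thresholdPlaques(getChannel(rec$fov, "plaque"), method = thresholdValue)
    seg <- segmentPlaques(pm, pixelSizeUm)
    cents <- as.matrix(rec$truth@microgliaTable[, c("soma_x_px", "soma_y_px")])
    a <- classifyAssociation(cents, seg$labels > 0, pixelSizeUm, 5)
    data.frame(mouse = rec$mouse_id,
               af = sum(seg$records$area_um2) / fovSize(rec$fov)^2,
               n_pa = sum(a$association == "plaque_associated"),
               n_nonpa = sum(a$association == "non_plaque_associated"))
  })
  df <- do.call(rbind, rows)
  aggregate(cbind(af, n_pa, n_nonpa) ~ mouse, df, mean)
}
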