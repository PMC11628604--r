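# Soma detection, body/process split, closing, distance fusion, watershed.

test_that("detectSomata finds isolated somata near their true centers", {
  g <- generateFov(groupSpec("APOE3", plaqueDensity = 0, microgliaBaseDensity = 20),
                   seed = 6, pixelSizeUm = 1.72)
  som <- detectSomata(getChannel(g$fov, "microglia"), 1.72)
  truthC <- as.matrix(g$truth@microgliaTable[, c("soma_x_px", "soma_y_px")])
  expect_equal(nrow(som$centroids), nrow(truthC), tolerance = 0.15)
  hits <- vapply(seq_len(nrow(truthC)), function(i) {
    min(sqrt((som$centroids[, 1] - truthC[i, 1])^2 +
             (som$centroids[, 2] - truthC[i, 2])^2)) <= 2
  }, logical(1))
  expect_gt(mean(hits), 0.9)

  blank <- detectSomata(matrix(0, 64, 64), 1)
  expect_identical(nrow(blank$centroids), 0L)

  ext <- detectSomata(matrix(0, 64, 64), 1,
                      centroids = cbind(c(5, 10, 15, 20, 25), 7))
  expect_identical(nrow(ext$centroids), 5L)
  expect_equal(ext$centroids[, 1], c(5, 10, 15, 20, 25))
})

test_that("splitBodyProcess thresholds thickness by the EDT", {
  cfg <- fusionConfig(bodyRadiusUm = 3)
  disk <- diskMask(64, 32, 32, 12)           # 6 um radius at 0.5 um/px
  sp <- splitBodyProcess(disk, cfg, 0.5)
  expect_true(all(sp$body | sp$process | !disk))
  expect_false(any(sp$body & sp$process))
  expect_true(all((sp$body | sp$process) == disk))
  # body is the inner disk of radius 3 um = 6 px (+/- 1 px discretization)
  inner <- diskMask(64, 32, 32, 7)
  outerD <- diskMask(64, 32, 32, 5)
  expect_true(all(sp$body[outerD[]] | !outerD[]))
  expect_true(all(!sp$body[!inner]))

  line <- matrix(FALSE, 32, 32); line[5:28, 16] <- TRUE
  spl <- splitBodyProcess(line, cfg, 0.5)
  expect_false(any(spl$body))
  expect_identical(spl$process, line)

  spe <- splitBodyProcess(matrix(FALSE, 8, 8), cfg, 0.5)
  expect_false(any(spe$body) || any(spe$process))
})

test_that("closeProcesses repairs small gaps and is idempotent on solids", {
  cfg <- fusionConfig(closingRadiusPx = 2)
  line <- matrix(FALSE, 32, 32)
  line[5:14, 16] <- TRUE; line[16:28, 16] <- TRUE  # 1 px gap
  closed <- closeProcesses(line, cfg)
  lab <- EBImage::bwlabel(EBImage::Image(closed * 1))
  expect_equal(max(lab), 1)

  solid <- diskMask(32, 16, 16, 8)
  expect_identical(closeProcesses(solid, cfg), solid)
  expect_false(any(closeProcesses(matrix(FALSE, 16, 16), cfg)))
})

test_that("fuseDistance computes the weighted EDT sum with zero outside", {
  cfg <- fusionConfig(wSoma = 2, wProc = 1)
  full <- diskMask(64, 32, 32, 20)
  soma <- diskMask(64, 32, 32, 8)
  fused <- fuseDistance(full, soma, cfg)
  expect_equal(fused[1, 1], 0)
  expect_true(all(fused[!full] == 0))
  # at the center: wProc * 20 + wSoma * 8 in px units (EDT to the px grid edge)
  expect_equal(fused[32, 32], 1 * 20 + 2 * 8, tolerance = 1.5)
  # empty soma: pure full-mask EDT
  f2 <- fuseDistance(full, matrix(FALSE, 64, 64), cfg)
  expect_equal(max(abs(f2 - 1 * gliaQuant:::distanceInMask(full))), 0)
  expect_error(fusionConfig(wSoma = 1, wProc = 2), "wSoma > wProc")
})

test_that("watershed partitions the mask, splits symmetric pairs, floods alone", {
  # single disk, single central seed
  disk <- diskMask(48, 24, 24, 15)
  f <- fuseDistance(disk, diskMask(48, 24, 24, 4), fusionConfig())
  lab <- watershedInstances(f, rbind(c(24, 24)), disk)
  expect_true(all((lab == 1) == disk))

  # two overlapping equal disks: mirror-symmetric split within 1%
  m <- diskMask(64, 25, 32, 10) | diskMask(64, 40, 32, 10)
  soma <- matrix(FALSE, 64, 64); soma[25, 32] <- TRUE; soma[40, 32] <- TRUE
  f2 <- fuseDistance(m, soma, fusionConfig())
  lab2 <- watershedInstances(f2, rbind(c(25, 32), c(40, 32)), m)
  expect_true(all((lab2 > 0) == m))
  a1 <- sum(lab2 == 1); a2 <- sum(lab2 == 2)
  expect_lte(abs(a1 - a2), 0.01 * max(a1, a2))

  # two separated cells but only one seed: both carry the single label
  m3 <- diskMask(64, 16, 16, 6) | diskMask(64, 48, 48, 6)
  f3 <- fuseDistance(m3, matrix(FALSE, 64, 64), fusionConfig())
  lab3 <- watershedInstances(f3, rbind(c(16, 16)), m3)
  expect_true(all((lab3 == 1) == m3))

  expect_error(watershedInstances(f3, matrix(numeric(), 0, 2), m3), "no seeds")
  expect_warning(watershedInstances(f3, rbind(c(16, 16), c(2, 60)), m3), "dropped")
})

test_that("non-overlapping convex cells get nearest-seed assignments", {
  n <- 96
  centers <- rbind(c(20, 20), c(70, 25), c(30, 70), c(75, 75))
  m <- Reduce(`|`, lapply(1:4, function(i) diskMask(n, centers[i, 1], centers[i, 2], 10)))
  soma <- Reduce(`|`, lapply(1:4, function(i) diskMask(n, centers[i, 1], centers[i, 2], 3)))
  lab <- watershedInstances(fuseDistance(m, soma, fusionConfig()), centers, m)
  idx <- which(m, arr.ind = TRUE)
  nearest <- apply(idx, 1, function(p)
    which.min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2))
  expect_identical(as.integer(lab[idx]), as.integer(nearest))
})

test_that("watershed labelling is deterministic", {
  g <- generateFov(groupSpec("APOE3", plaqueDensity = 0, microgliaBaseDensity = 40),
                   seed = 14, pixelSizeUm = 1.72)
  mask <- g$truth@microgliaLabels > 0
  seeds <- as.matrix(g$truth@microgliaTable[, c("soma_x_px", "soma_y_px")])
  soma <- truthSomaMask(g$truth, 1.72, dim(mask))
  f <- fuseDistance(mask, soma, fusionConfig())
  l1 <- suppressWarnings(watershedInstances(f, seeds, mask))
  l2 <- suppressWarnings(watershedInstances(f, seeds, mask))
  expect_identical(l1, l2)
  # partition and seed fidelity
  expect_true(all((l1 > 0) == mask))
  inMask <- mask[cbind(round(seeds[, 1]), round(seeds[, 2]))]
  sIdx <- cbind(round(seeds[inMask, 1]), round(seeds[inMask, 2]))
  expect_identical(as.integer(l1[sIdx]), which(inMask))
})

test_that("segmentMicroglia recovers most cells one-to-one on a dense field", {
  g <- generateFov(groupSpec("APOE3", plaqueDensity = 0, microgliaBaseDensity = 60),
                   seed = 9, pixelSizeUm = 0.86)
  tr <- g$truth
  mask <- tr@microgliaLabels > 0
  seeds <- as.matrix(tr@microgliaTable[, c("soma_x_px", "soma_y_px")])
  res <- suppressWarnings(segmentMicroglia(getChannel(g$fov, "microglia"), mask,
                                           0.86, centroids = seeds))
  # evaluate the assignment on the semantic mask support (the closing stage
  # legitimately grows the working mask to repair process continuity)
  pred <- res$labels
  pred[!mask] <- 0L
  k <- nrow(seeds)
  matched <- matchInstances(tr@microgliaLabels, pred, k)
  expect_gt(matched / k, 0.9)
})
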