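# Synthetic image, spot-field and cohort generators.

test_that("generateFov handles the empty case and is deterministic", {
  spec <- groupSpec("APOEKO", plaqueDensity = 0, microgliaBaseDensity = 5)
  g1 <- generateFov(spec, seed = 3, pixelSizeUm = 3.44)
  expect_identical(nrow(g1$truth@plaqueTable), 0L)
  expect_true(all(g1$truth@plaqueLabels == 0L))
  # plaque channel is pure noise: nothing above the staining floor
  expect_lt(max(getChannel(g1$fov, "plaque")), 0.4)

  g2 <- generateFov(spec, seed = 3, pixelSizeUm = 3.44)
  expect_identical(g1$fov@pixels, g2$fov@pixels)
  expect_identical(g1$truth@microgliaTable, g2$truth@microgliaTable)

  g3 <- generateFov(spec, seed = 4, pixelSizeUm = 3.44)
  expect_false(identical(getChannel(g1$fov, "microglia"),
                         getChannel(g3$fov, "microglia")))
})

test_that("ground truth counts match rendered instances and calibration", {
  spec <- groupSpec("APOE4", plaqueDensity = 6)
  g <- generateFov(spec, seed = 8, pixelSizeUm = 1.72)
  tr <- g$truth
  expect_identical(sort(unique(as.vector(tr@plaqueLabels[tr@plaqueLabels > 0]))),
                   seq_len(nrow(tr@plaqueTable)))
  expect_true(max(tr@microgliaLabels) <= nrow(tr@microgliaTable))
  expect_identical(length(tr@branches), nrow(tr@microgliaTable))
  # calibration invariant: pixel count times pixel size equals the field size
  d <- dim(getChannel(g$fov, "plaque"))
  expect_lt(abs(d[1] * pixelSize(g$fov) - fovSize(g$fov)), pixelSize(g$fov))
  # every labelled pixel maps to exactly one instance by construction
  expect_true(all(tr@plaqueLabels >= 0))
})

test_that("true process length equals the summed branch polyline length", {
  g <- generateFov(groupSpec("APOE3", plaqueDensity = 0, microgliaBaseDensity = 6),
                   seed = 5, pixelSizeUm = 1.72)
  tr <- g$truth
  for (k in seq_len(nrow(tr@microgliaTable))) {
    polyLen <- sum(vapply(tr@branches[[k]], function(b) {
      if (nrow(b) < 2) return(0)
      sum(sqrt(rowSums((b[-1, , drop = FALSE] - b[-nrow(b), , drop = FALSE])^2)))
    }, numeric(1))) * pixelSize(g$fov)
    expect_equal(tr@microgliaTable$process_length_um[k], polyLen, tolerance = 1e-10)
  }
})

test_that("microglia density within 5 um of plaque edges exceeds background", {
  spec <- groupSpec("APOE4", plaqueDensity = 10)
  nearEdge <- 0; nearArea <- 0; far <- 0; farArea <- 0
  for (s in 1:5) {
    g <- generateFov(spec, seed = 400 + s, pixelSizeUm = 1.72, channels = "plaque")
    tr <- g$truth; tab <- tr@microgliaTable; pt <- tr@plaqueTable
    edgeDist <- vapply(seq_len(nrow(tab)), function(k) {
      min(sqrt((pt$cx_px - tab$soma_x_px[k])^2 + (pt$cy_px - tab$soma_y_px[k])^2) *
            1.72 - pt$radius_um)
    }, numeric(1))
    band <- sum(2 * pi * pt$radius_um * 5)             # ~band area, um^2
    tot <- fovSize(g$fov)^2
    nearEdge <- nearEdge + sum(edgeDist >= 0 & edgeDist <= 5)
    nearArea <- nearArea + band
    far <- far + sum(edgeDist > 20)
    farArea <- farArea + (tot - band - sum(pi * (pt$radius_um + 20)^2))
  }
  expect_gt(nearEdge / nearArea, far / farArea)
})

test_that("simpull frames have Poisson spot counts at recorded positions", {
  g0 <- generateSimpullFov(groupSpec("APOE2", spotRate = 0), seed = 2)
  expect_identical(nrow(g0$truth@spotPositions), 0L)

  g1 <- generateSimpullFov(groupSpec("APOE2", spotRate = 40), seed = 2)
  g2 <- generateSimpullFov(groupSpec("APOE2", spotRate = 40), seed = 2)
  expect_identical(g1$truth@spotPositions, g2$truth@spotPositions)
  expect_identical(g1$fov@pixels, g2$fov@pixels)

  # rendered intensity peaks near each recorded position
  fr <- getChannel(g1$fov, "spots")
  bg <- median(fr)
  pos <- g1$truth@spotPositions
  vals <- fr[cbind(round(pos[, 1]), round(pos[, 2]))]
  expect_gt(mean(vals > bg + 0.05), 0.9)
})

test_that("cohort dose-response has the configured deterministic structure", {
  # zero slope, zero noise: identical abeta for all mice in the group
  cc <- cohortConfig(groups = list(groupSpec("APOE4", abetaSlope = 0, abetaNoiseSd = 0)),
                     micePerGroup = 5, seed = 11)
  co <- generateCohort(cc, renderImages = FALSE)
  expect_equal(sd(co$table$abeta42), 0, tolerance = 1e-12)

  # treatment offset -100 with zero noise: exact recovery by multiple regression
  gs <- list(groupSpec("APOE4", abetaSlope = 0.2, abetaNoiseSd = 0),
             groupSpec("APOE4", treatment = "PLX3397", abetaTreatmentOffset = -100,
                       abetaSlope = 0.2, abetaNoiseSd = 0))
  co2 <- generateCohort(cohortConfig(groups = gs, micePerGroup = 6, seed = 12),
                        renderImages = FALSE)
  r <- multipleRegression(co2$table$abeta42,
                          co2$table$treatment == "PLX3397",
                          co2$table$apoe_level)
  expect_equal(r$beta_treatment, -100, tolerance = 1e-9)
  expect_equal(r$coefficients$estimate[r$coefficients$term == "covariate"], 0.2,
               tolerance = 1e-9)
})

test_that("cohort OLS slope is unbiased over replicate cohorts", {
  # empirical mean slope within 3 standard errors of the configured 0.23
  slopes <- vapply(1:200, function(s) {
    cc <- cohortConfig(groups = list(groupSpec("APOE4")), micePerGroup = 8,
                       seed = 7000 + s)
    co <- generateCohort(cc, renderImages = FALSE)
    olsFit(co$table$apoe_level, co$table$abeta42)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.23), 3 * se)
})

test_that("PLX3397 groups carry the reported depletion fractions", {
  e4 <- groupSpec("APOE4")
  e4t <- groupSpec("APOE4", treatment = "PLX3397")
  expect_equal(e4t@microgliaBaseDensity / e4@microgliaBaseDensity, 1 - 0.87,
               tolerance = 1e-12)
  e3t <- groupSpec("APOE3", treatment = "PLX3397")
  expect_equal(e3t@paRecruitmentCoeff / groupSpec("APOE3")@paRecruitmentCoeff,
               1 - 0.77, tolerance = 1e-12)
})
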