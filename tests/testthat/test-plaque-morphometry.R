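# Plaque instance segmentation, co-occurrence texture and ASM compactness.

test_that("segmentPlaques applies the ~4 um floor and the stated size bins", {
  n <- 128
  # 3 um disk only: below the floor
  m3 <- diskMask(n, 30, 30, 1.5)   # at 1 um/px, diameter 3 um
  expect_identical(nrow(segmentPlaques(m3, 1)$records), 0L)

  # 25 um and 45 um disks: medium and large
  m <- diskMask(n, 32, 32, 12.5) | diskMask(n, 90, 90, 22.5)
  seg <- segmentPlaques(m, 1)
  expect_identical(nrow(seg$records), 2L)
  expect_setequal(as.character(seg$records$size_class), c("medium", "large"))
  # equivalent diameter consistent with area
  expect_equal(seg$records$equivalent_diameter_um,
               2 * sqrt(seg$records$area_um2 / pi), tolerance = 1e-12)

  empty <- segmentPlaques(matrix(FALSE, 16, 16), 1)
  expect_identical(nrow(empty$records), 0L)
  s <- summarizeFovPlaques(empty$records, 256)
  expect_identical(s$n_plaques, 0L)
  expect_identical(s$area_fraction, 0)
})

test_that("segmentation count matches ground truth on non-overlapping plaques", {
  for (s in 1:3) {
    g <- generateFov(groupSpec("APOE3", plaqueDensity = 5, microgliaBaseDensity = 0),
                     seed = 50 + s, pixelSizeUm = 1.72, channels = "plaque")
    tr <- g$truth
    if (nrow(tr@plaqueTable) == 0) next
    # use the ground-truth mask itself: counts must agree exactly when the
    # rendered disks do not touch
    lab <- tr@plaqueLabels
    touching <- any(vapply(seq_len(nrow(tr@plaqueTable)), function(i) {
      others <- tr@plaqueTable[-i, ]
      any(sqrt((others$cx_px - tr@plaqueTable$cx_px[i])^2 +
               (others$cy_px - tr@plaqueTable$cy_px[i])^2) * 1.72 <
            (others$radius_um + tr@plaqueTable$radius_um[i]))
    }, logical(1)))
    if (touching) next
    seg <- segmentPlaques(lab > 0, 1.72)
    expect_identical(nrow(seg$records), nrow(tr@plaqueTable))
  }
})

test_that("computeGlcm matches hand-enumerated examples", {
  # [x, y] patch whose y-offset pairs are (0,0) and (1,1)
  patch <- rbind(c(0, 0), c(1, 1))
  g <- computeGlcm(patch, matrix(TRUE, 2, 2), levels = 2)
  expect_equal(g[["90"]], matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # the x-offset pairs are (0,1) twice
  expect_equal(g[["0"]], matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # constant patch: single diagonal entry at every angle
  gc <- computeGlcm(matrix(5, 4, 4), matrix(TRUE, 4, 4), levels = 8)
  for (a in names(gc)) {
    expect_equal(sum(gc[[a]]), 1)
    expect_equal(gc[[a]][1, 1], 1)
  }

  # two-level checkerboard: all mass off-diagonal on the x offset
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  gcb <- computeGlcm(cb, matrix(TRUE, 8, 8), levels = 2)
  expect_equal(gcb[["0"]][1, 2], 0.5)
  expect_equal(gcb[["0"]][2, 1], 0.5)
})

test_that("computeGlcm equals the brute-force double-loop oracle exactly", {
  set.seed(9)
  offsets <- list("0" = c(1L, 0L), "45" = c(1L, 1L),
                  "90" = c(0L, 1L), "135" = c(-1L, 1L))
  for (rep in 1:10) {
    patch <- matrix(runif(32 * 32), 32, 32)
    mask <- matrix(runif(32 * 32) > 0.4, 32, 32)
    if (sum(mask) < 2) next
    glcms <- computeGlcm(patch, mask)
    for (a in names(glcms)) {
      oracle <- bruteGlcm(patch, mask, 64L, offsets[[a]])
      expect_equal(glcms[[a]], oracle, tolerance = 1e-12)
    }
  }
})

test_that("ASM has its closed-form values and analytic bounds", {
  # constant patch
  expect_equal(computeAsm(computeGlcm(matrix(1, 6, 6), matrix(TRUE, 6, 6))), 1)
  # checkerboard: two entries of 0.5; orthogonal angles are exactly 0.5,
  # diagonal angles differ by one pair on an even board (odd pair count)
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  gcb <- computeGlcm(cb, matrix(TRUE, 16, 16), levels = 2)
  expect_equal(sum(gcb[["0"]]^2), 0.5, tolerance = 1e-12)
  expect_equal(sum(gcb[["90"]]^2), 0.5, tolerance = 1e-12)
  expect_equal(computeAsm(gcb), 0.5, tolerance = 1e-4)
  # iid uniform noise over 64 levels approaches 1/4096, far below 1
  set.seed(4)
  noise <- matrix(runif(96 * 96), 96, 96)
  asmNoise <- computeAsm(computeGlcm(noise, matrix(TRUE, 96, 96)))
  expect_lt(asmNoise, 0.001)
  expect_gt(asmNoise, 1 / 4096 / 3)
  expect_warning(res <- computeAsm(list()), "no defined")
  expect_true(is.na(res))
})

test_that("ASM is invariant to affine intensity rescaling", {
  set.seed(5)
  patch <- matrix(runif(40 * 40), 40, 40)
  mask <- diskMask(40, 20, 20, 15)
  a1 <- computeAsm(computeGlcm(patch, mask))
  a2 <- computeAsm(computeGlcm(3.7 * patch + 11, mask))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("median ASM increases strictly with the generative core fraction", {
  meds <- vapply(c(0.2, 0.5, 0.9), function(cf) {
    g <- generateFov(groupSpec("APOE4", plaqueDensity = 50,
                               coreFractionShape1 = 1e6 * cf,
                               coreFractionShape2 = 1e6 * (1 - cf)),
                     seed = 33, pixelSizeUm = 0.86, channels = "plaque")
    rec <- data.frame(plaque_id = g$truth@plaqueTable$plaque_id, asm = NA_real_)
    rec <- plaqueAsm(getChannel(g$fov, "plaque"), g$truth@plaqueLabels, rec)
    median(rec$asm, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("FOV summaries report counts, area fraction and class proportions", {
  rec <- data.frame(plaque_id = 1:10,
                    cx_um = 0, cy_um = 0,
                    area_um2 = c(rep(100, 6), rep(500, 4)),
                    equivalent_diameter_um = c(rep(11.3, 6), rep(25.2, 4)),
                    asm = 0.5,
                    size_class = factor(c(rep("small", 6), rep("medium", 4)),
                                        levels = c("small", "medium", "large")),
                    border_touching = FALSE)
  s <- summarizeFovPlaques(rec, 60000)
  expect_identical(s$n_plaques, 10L)
  expect_equal(s$area_fraction, 2600 / 60000)
  expect_equal(s$prop_medium, 0.4)
  expect_identical(s$n_large, 0L)
})
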