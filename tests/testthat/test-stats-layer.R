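# Regression, group comparisons, mixed models, multi-set intersection.

test_that("olsFit matches closed-form values and the normal-equation oracle", {
  r <- olsFit(0:2, c(0, 1, 2)) # exact fit
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)

  rc <- olsFit(c(1, 2, 3, 4), rep(5, 4))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)

  set.seed(10)
  x <- rnorm(10, 40, 10); y <- 200 + 0.23 * x + rnorm(10, 0, 3)
  r2 <- olsFit(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)

  expect_error(olsFit(rep(1, 5), rnorm(5)), "constant")
  expect_error(olsFit(1:2, 1:2), "at least 3")
})

test_that("multipleRegression is exact on noise-free designs and calibrated", {
  apoe <- c(30, 40, 50, 60, 35, 45, 55, 65)
  treat <- rep(c(0, 1), each = 4)
  y <- 100 + 0.2 * apoe - 100 * treat
  r <- multipleRegression(y, treat, apoe)
  expect_equal(r$beta_treatment, -100, tolerance = 1e-10)
  expect_equal(r$coefficients$estimate[r$coefficients$term == "covariate"], 0.2,
               tolerance = 1e-10)

  # matches the two-predictor normal equations
  set.seed(3)
  y2 <- rnorm(40); t2 <- rbinom(40, 1, 0.5); c2 <- rnorm(40)
  r2 <- multipleRegression(y2, t2, c2)
  X <- cbind(1, t2, c2)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(unname(r2$coefficients$estimate), unname(as.vector(beta)),
               tolerance = 1e-10)

  # permutation calibration of the treatment p-value under the null
  set.seed(4)
  y3 <- rnorm(40); c3 <- rnorm(40)
  rej <- mean(vapply(1:200, function(i) {
    multipleRegression(y3, sample(rep(c(0, 1), 20)), c3)$p_treatment < 0.05
  }, logical(1)))
  expect_gte(rej, 0.02); expect_lte(rej, 0.09)

  expect_error(multipleRegression(rnorm(10), rep(1, 10), rnorm(10)), "vary")
})

test_that("ANOVA/Tukey and the t-test behave on null and separated groups", {
  set.seed(5)
  v <- rnorm(10)
  r <- anovaTukey(list(a = v, b = v, c = v)) # literally identical groups
  expect_lt(r$f, 1e-20)
  expect_true(all(r$tukey$p_adj > 0.999))

  sep <- list(a = rnorm(10), b = rnorm(10, 10)) # 10 SD apart
  r2 <- anovaTukey(sep)
  expect_lt(r2$tukey$p_adj[1], 1e-6)

  t2 <- unpairedT(sep$a, sep$b)
  expect_lt(t2$p, 1e-6)
  expect_equal(t2$df, 18)
  tw <- unpairedT(sep$a, sep$b, welch = TRUE)
  expect_lt(tw$df, 18 + 1e-9)

  # zero-variance group at n = 2 is computed but flagged
  r3 <- anovaTukey(list(a = c(1, 1), b = c(2, 3), c = c(4, 6)))
  expect_identical(r3$flagged, "a")
  expect_error(anovaTukey(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("the gaussian LMM degenerates to pooled OLS without mouse variance", {
  set.seed(6)
  d <- data.frame(diameter = runif(200, 10, 60),
                  mouse = factor(rep(1:10, each = 20)))
  d$asm <- exp(2 - 0.01 * d$diameter + rnorm(200, 0, 0.1)) # no mouse effect
  r <- suppressWarnings(
    fitMixedModel(d, "asm", "diameter", "mouse", "gaussian", logResponse = TRUE))
  expect_lt(r$randomInterceptVar, 0.005)
  pooled <- lm(log(asm) ~ diameter, data = d)
  expect_equal(r$fixed$estimate[r$fixed$term == "diameter"],
               unname(coef(pooled)["diameter"]), tolerance = 1e-3)
  expect_error(fitMixedModel(d[d$mouse == "1", ], "asm", "diameter", "mouse"),
               ">= 2 levels")
})

test_that("mixed models recover known fixed effects", {
  set.seed(7)
  # log-ASM with mouse intercept SD 0.3 and diameter slope -0.01
  est <- vapply(1:20, function(i) {
    mouse <- rep(1:20, each = 30)
    diam <- runif(600, 10, 60)
    y <- exp(1 + rnorm(20, 0, 0.3)[mouse] - 0.01 * diam + rnorm(600, 0, 0.2))
    d <- data.frame(asm = y, diameter = diam, mouse = factor(mouse))
    r <- fitMixedModel(d, "asm", "diameter", "mouse", "gaussian",
                       logResponse = TRUE)
    r$fixed$estimate[r$fixed$term == "diameter"]
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.01)) / 0.01, 0.10)

  # binomial GLMM with log-odds group effect 1.0
  est2 <- vapply(1:20, function(i) {
    mouse <- rep(1:16, each = 40)
    grp <- rep(c(0, 1), each = 320)
    eta <- -0.5 + 1.0 * grp + rnorm(16, 0, 0.4)[mouse]
    d <- data.frame(y = rbinom(640, 1, plogis(eta)), grp = grp,
                    mouse = factor(mouse))
    r <- suppressWarnings(fitMixedModel(d, "y", "grp", "mouse", "binomial"))
    r$fixed$estimate[r$fixed$term == "grp"]
  }, numeric(1))
  expect_lt(abs(mean(est2) - 1), 0.15)
})

test_that("multisetExactTest matches closed forms, enumeration and hypergeometric", {
  # m = 2, N = 10, two 5-sets, k = 3: hypergeometric tail 126/252
  r <- multisetExactTest(10, c(5, 5), 3)
  expect_equal(r$tailP, 0.5, tolerance = 1e-12)
  expect_equal(sum(r$pmf), 1, tolerance = 1e-9)

  # forced full overlap
  expect_equal(multisetExactTest(3, c(3, 3, 3), 3)$pmf[["3"]], 1, tolerance = 1e-12)
  # exhaustive enumeration for N = 4, three 3-sets
  expect_equal(multisetExactTest(4, c(3, 3, 3), 3)$pmf[["3"]], 1 / 16,
               tolerance = 1e-12)

  # full exhaustive enumeration oracle, N = 6, sizes (3, 2, 2)
  sets1 <- combn(6, 3, simplify = FALSE)
  sets2 <- combn(6, 2, simplify = FALSE)
  tally <- numeric(3)
  for (a in sets1) for (b in sets2) for (cc in sets2) {
    k <- length(intersect(intersect(a, b), cc))
    tally[k + 1] <- tally[k + 1] + 1
  }
  enum <- tally / sum(tally)
  got <- multisetExactTest(6, c(3, 2, 2), 0)
  expect_equal(unname(got$pmf), enum, tolerance = 1e-12)

  # reduces to dhyper at m = 2 to 1e-12 relative error
  r2 <- multisetExactTest(500, c(60, 40), 5)
  hy <- dhyper(0:40, 60, 440, 40)
  expect_lt(max(abs(r2$pmf - hy) / pmax(hy, 1e-300)), 1e-12)

  expect_error(multisetExactTest(10, c(5, 3), 4), "smallest set")
})

test_that("pmf sums to 1 across set configurations and sizes", {
  set.seed(8)
  for (i in 1:10) {
    N <- sample(20:60, 1)
    m <- sample(2:4, 1)
    sizes <- sample.int(N, m, replace = TRUE)
    r <- multisetExactTest(N, sizes, 0)
    expect_lt(abs(sum(r$pmf) - 1), 1e-9)
    expect_true(all(r$pmf >= 0))
  }
})

test_that("enrichment tests give hypergeometric and Fisher exact values", {
  r0 <- enrichmentTests(10, 12, 0, 100)
  expect_equal(r0$p_hypergeometric, 1)

  rf <- enrichmentTests(10, 12, 1, 24)
  expect_equal(rf$p_fisher, fisher.test(matrix(c(1, 11, 9, 3), 2, 2))$p.value,
               tolerance = 1e-12)
  expect_equal(rf$p_fisher, 0.00276, tolerance = 1e-3)

  # hypergeometric matches multisetExactTest at m = 2 to 1e-12 relative
  rh <- enrichmentTests(40, 60, 9, 500, nTests = 10)
  rm2 <- multisetExactTest(500, c(40, 60), 9)
  expect_lt(abs(rh$p_hypergeometric - rm2$tailP) / rm2$tailP, 1e-12)
  expect_equal(rh$p_hypergeometric_adj,
               min(1, rh$p_hypergeometric * 10), tolerance = 1e-12)

  expect_error(enrichmentTests(10, 12, 13, 24), "inconsistent")
})
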