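# Statistical layer: dose-response OLS, confounder-adjusted multiple
# regression, group comparisons, and mixed-effects contracts.

#' Simple linear regression (dose-response fit)
#'
#' Least-squares fit of `y` on `x` with R-squared and a two-sided t-test on
#' the slope, as used for APOE level vs guanidine-soluble A-beta-42.
#'
#' @param x,y numeric vectors (n >= 3, x non-constant).
#' @return list `slope, intercept, se_slope, r_squared, p, n, fit`.
#' @examples
#' olsFit(0:2, c(0, 1, 2))$slope # 1
#' @export
olsFit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) < .Machine$double.eps) stop("x is constant: slope undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  r2 <- sm$r.squared
  if (is.nan(r2)) r2 <- 0  # constant response: no variance to explain
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       se_slope = unname(co["x", "Std. Error"]),
       r_squared = r2,
       p = unname(co["x", "Pr(>|t|)"]),
       n = length(x), fit = fit)
}

#' Multiple regression with a treatment indicator and a covariate
#'
#' `y ~ treatment + covariate`; the treatment coefficient is the reported
#' contrast (e.g. A-beta-42 shift under microglial depletion adjusted for
#' APOE level).
#'
#' @param y response.
#' @param treatment 0/1 (or logical/factor) treatment indicator.
#' @param covariate numeric confounder.
#' @return list with per-coefficient `coefficients` data.frame
#'   (`term, estimate, se, t, p`), `beta_treatment, se_treatment,
#'   p_treatment, r_squared, n, fit`.
#' @export
multipleRegression <- function(y, treatment, covariate) {
  treatment <- as.numeric(as.logical(as.numeric(treatment)))
  if (sd(treatment) < .Machine$double.eps || sd(covariate) < .Machine$double.eps)
    stop("both predictors must vary")
  if (length(y) <= 3L) stop("need more than 3 observations")
  dat <- data.frame(y = y, treatment = treatment, covariate = covariate)
  fit <- lm(y ~ treatment + covariate, data = dat)
  if (any(!is.finite(coef(fit))) || fit$rank < 3L)
    stop("collinear design: coefficients not estimable")
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    t = co[, 3], p = co[, 4], row.names = NULL)
  list(coefficients = tab,
       beta_treatment = unname(co["treatment", 1]),
       se_treatment = unname(co["treatment", 2]),
       p_treatment = unname(co["treatment", 4]),
       r_squared = sm$r.squared, n = length(y), fit = fit)
}

#' One-way ANOVA with Tukey's multiple-comparison test
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @return list `f, p, tukey` (data.frame `comparison, diff, p_adj`),
#'   `flagged` (groups with zero variance at n = 2).
#' @examples
#' r <- anovaTukey(list(a = rnorm(10), b = rnorm(10, 5)))
#' r$p < 0.01
#' @export
anovaTukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2")
  flagged <- names(groups)[vapply(groups, function(g)
    length(g) == 2L && sd(g) < .Machine$double.eps, logical(1))]
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1))),
               levels = names(groups))
  )
  fit <- aov(y ~ g, data = dat)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(f = sm["g", "F value"], p = sm["g", "Pr(>F)"],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       flagged = flagged)
}

#' Unpaired two-sample t-test
#'
#' @param a,b numeric samples.
#' @param welch use the Welch correction (default FALSE: pooled variance).
#' @return list `t, df, p, mean_diff`.
#' @export
unpairedT <- function(a, b, welch = FALSE) {
  r <- t.test(a, b, var.equal = !welch)
  list(t = unname(r$statistic), df = unname(r$parameter), p = r$p.value,
       mean_diff = unname(diff(rev(r$estimate))))
}

#' Random-intercept mixed-effects model
#'
#' Gaussian family: linear mixed model fit by REML; binomial family:
#' logistic GLMM (Laplace). The random intercept absorbs between-mouse
#' variability; fixed-effect p-values are two-sided Wald z. Residual
#' quantiles are returned for Q-Q normality checks.
#'
#' @param data a data.frame.
#' @param response response column name; for the binomial family either a
#'   0/1 column or a two-column `cbind(successes, failures)` expression
#'   passed as a string.
#' @param fixed character vector of fixed-effect column names (may be empty
#'   for an intercept-only model).
#' @param grouping random-intercept grouping column (>= 2 levels).
#' @param family `"gaussian"` or `"binomial"`.
#' @param logResponse log-transform the response first (gaussian only).
#' @return list `fixed` (data.frame `term, estimate, se, z, p`),
#'   `randomInterceptVar`, `singular`, `residualQuantiles`, `fit`.
#' @export
fitMixedModel <- function(data, response, fixed = character(), grouping,
                          family = c("gaussian", "binomial"),
                          logResponse = FALSE) {
  family <- match.arg(family)
  stopifnot(grouping %in% names(data))
  if (length(unique(data[[grouping]])) < 2L)
    stop("grouping factor needs >= 2 levels")
  dat <- data
  lhs <- response
  if (logResponse) {
    if (family != "gaussian") stop("logResponse applies to the gaussian family")
    dat$.logresp <- log(dat[[response]])
    lhs <- ".logresp"
  }
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 paste0("(1|", grouping, ")")), collapse = " + ")
  fml <- as.formula(paste(lhs, "~", rhs))
  fit <- if (family == "gaussian") {
    lme4::lmer(fml, data = dat, REML = TRUE)
  } else {
    lme4::glmer(fml, data = dat, family = binomial())
  }
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: random-intercept variance is (near) zero")
  co <- as.data.frame(coef(summary(fit)))
  z <- co[, "Estimate"] / co[, "Std. Error"]
  out <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], z = z,
                    p = 2 * pnorm(-abs(z)), row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  riVar <- vc$vcov[vc$grp == grouping][1]
  list(fixed = out, randomInterceptVar = riVar, singular = singular,
       residualQuantiles = quantile(residuals(fit), seq(0.01, 0.99, 0.01)),
       fit = fit)
}
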