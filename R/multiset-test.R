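# Exact distribution of the common intersection of m independent uniform
# fixed-size subsets of a background of size N, and enrichment tests.

logSumExp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Exact multi-set intersection test
#'
#' Distribution of `X = |S_1 ∩ ... ∩ S_m|` when each `S_j` is an independent
#' uniform subset of size `n_j` from a background of `N` elements, and the
#' upper tail `P(X >= k)` for an observed intersection of size `k`.
#'
#' The pmf is computed by sequential exact conditioning: given the running
#' intersection has size `t`, intersecting with the next subset of size
#' `n_j` yields a hypergeometric size, so the pmf is an iterated
#' hypergeometric convolution. All terms are positive, so the computation is
#' stable in log space up to backgrounds of tens of thousands of genes and
#' reduces exactly to the hypergeometric distribution at `m = 2`.
#'
#' @param N background size.
#' @param setSizes integer vector `n_1..n_m` (each <= N), m >= 2.
#' @param kObserved observed intersection size (<= min(setSizes)).
#' @param nTests Bonferroni multiplicity (default 1).
#' @return object of class `"MultiSetTestResult"`: list with
#'   `backgroundSize, setSizes, observed, support, pmf, tailP, bonferroniP`.
#' @examples
#' multisetExactTest(10, c(5, 5), 3)$tailP  # 0.5
#' multisetExactTest(4, c(3, 3, 3), 3)$pmf[["3"]] # 1/16
#' @export
multisetExactTest <- function(N, setSizes, kObserved, nTests = 1L) {
  setSizes <- as.numeric(setSizes)
  if (length(setSizes) < 2L) stop("need at least two sets")
  if (any(setSizes > N) || any(setSizes < 0)) stop("set sizes must be in [0, N]")
  if (kObserved > min(setSizes))
    stop("observed intersection exceeds the smallest set")
  # The intersection is symmetric in the sets, so process them smallest
  # first: the running intersection then never exceeds maxI = min(n_j).
  sizes <- sort(setSizes)
  maxI <- sizes[1]
  logv <- rep(-Inf, maxI + 1L)
  logv[maxI + 1L] <- 0 # point mass: the running intersection is S_(1) itself
  for (j in 2:length(sizes)) {
    nj <- sizes[j]
    newv <- rep(-Inf, maxI + 1L)
    for (s in 0:maxI) {
      ts <- s:maxI
      terms <- logv[ts + 1L] + dhyper(s, ts, N - ts, nj, log = TRUE)
      newv[s + 1L] <- logSumExp(terms)
    }
    logv <- newv
  }
  pmf <- exp(logv)
  tailP <- exp(logSumExp(logv[(kObserved:maxI) + 1L]))
  tailP <- min(tailP, 1)
  structure(list(
    backgroundSize = N, setSizes = setSizes, observed = kObserved,
    support = 0:maxI, pmf = setNames(pmf, 0:maxI),
    tailP = tailP, bonferroniP = min(1, tailP * nTests)
  ), class = "MultiSetTestResult")
}

#' @export
print.MultiSetTestResult <- function(x, ...) {
  cat("Exact multi-set intersection test\n")
  cat("  background N =", x$backgroundSize, "; set sizes:",
      paste(x$setSizes, collapse = ", "), "\n")
  cat("  observed intersection =", x$observed,
      "; P(X >=", paste0(x$observed, ")"), "=",
      format(x$tailP, digits = 4), "\n")
  invisible(x)
}

#' Hypergeometric enrichment and Fisher's exact test with Bonferroni control
#'
#' Upper-tail hypergeometric enrichment p for an `overlap` between a hit set
#' and a category drawn from a background of `N`, the two-sided Fisher exact
#' p of the corresponding 2 x 2 table, and their Bonferroni adjustments
#' (`p_adj = min(1, p * nTests)`).
#'
#' @param hitSize size of the hit set.
#' @param categorySize size of the category.
#' @param overlap observed overlap (<= min(hitSize, categorySize)).
#' @param N background size (>= hitSize, categorySize).
#' @param nTests Bonferroni multiplicity (supplied by the caller; default 1).
#' @return list `p_hypergeometric, p_hypergeometric_adj, p_fisher,
#'   p_fisher_adj, table`.
#' @examples
#' enrichmentTests(10, 12, 1, 24)$p_fisher # ~0.0028
#' @export
enrichmentTests <- function(hitSize, categorySize, overlap, N, nTests = 1L) {
  if (overlap > min(hitSize, categorySize) || max(hitSize, categorySize) > N ||
      overlap < 0)
    stop("inconsistent counts")
  d <- N - hitSize - categorySize + overlap
  if (d < 0) stop("inconsistent counts: table cell below zero")
  pHyper <- phyper(overlap - 1, categorySize, N - categorySize, hitSize,
                   lower.tail = FALSE)
  tab <- matrix(c(overlap, categorySize - overlap,
                  hitSize - overlap, d), 2, 2)
  pFisher <- fisher.test(tab)$p.value
  list(p_hypergeometric = pHyper,
       p_hypergeometric_adj = min(1, pHyper * nTests),
       p_fisher = pFisher,
       p_fisher_adj = min(1, pFisher * nTests),
       table = tab)
}
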