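#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). A constant
#' vector makes the coefficient undefined: `NA` is returned with a
#' warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Correlation in [-1, 1], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))`.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Non-negative scalar; 0 iff the vectors are identical.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) < 1L) stop("need at least one observation")
  sqrt(mean((observed - predicted)^2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted p-values over a family of `m` tests: sorted
#' ascending, `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the input order. `m` defaults to `length(p)` but may be
#' larger when the family is wider than the p-values at hand.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param m Family size.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m cannot be smaller than length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Format a permutation p-value for display
#'
#' A raw permutation p of exactly 0 is reported as a bound
#' (`"< 1/n_perm"`); other values are printed as given.
#'
#' @param p Raw p-value.
#' @param n_perm Number of permutations behind it.
#' @return Character scalar.
#' @export
format_perm_p <- function(p, n_perm) {
  if (is.na(p)) return("NA")
  if (p == 0) sprintf("< %.4g", 1 / n_perm) else sprintf("%.4g", p)
}

#' Compare two groups' iteration performance distributions
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between, e.g., the
#' female and male models' per-iteration Spearman rho values: exact when
#' both samples are small and untied, otherwise the normal approximation
#' with mid-ranks and tie correction.
#'
#' @param x,y Numeric performance vectors for the two groups.
#' @return List with `statistic` (rank-sum W), `p` and the `htest`
#'   object.
#' @export
compare_group_performance <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value, test = ht)
}

#' Permutation-based significance of a fitted CPM
#'
#' Re-runs the full CPM procedure (fresh fold partitions, edge selection,
#' fold models) `n_perm` times with the score vector randomly permuted
#' relative to the connectomes and covariates, recording each permuted
#' run's median out-of-fold Spearman rho. The non-parametric p-value is
#'
#' `p = #\{rho_null >= rho_median\} / n_perm`,
#'
#' the fraction of permuted medians at or above the unpermuted median
#' performance. Permuting the outcome only (leaving covariates attached
#' to the connectomes) preserves the confound structure under the null.
#' A raw p of 0 prints as `< 1/n_perm`.
#'
#' @param object A fitted `cpm`.
#' @param n_perm Number of permutations (default 1000).
#' @param n_iterations CV iterations per permuted run; defaults to the
#'   fitted object's count. The observed reference `rho_median` is the
#'   fitted object's median rho, so for a calibrated null use the same
#'   iteration count as the fit.
#' @param seed RNG seed for the permutations.
#' @return Object of class `cpm_perm`: `rho_null` (length `n_perm`),
#'   `rho_median`, raw `p`, `n_perm`.
#' @export
cpm_permute <- function(object, n_perm = 1000L,
                        n_iterations = object$n_iterations,
                        seed = object$seed + 1000003L) {
  stopifnot(inherits(object, "cpm"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be positive")
  X <- object$x; y <- object$y; C <- object$covariates
  pre <- cpm_precompute(X, C)
  rho_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      eng <- cpm_engine(X, yp, C, object$k, n_iterations, object$alpha,
                        object$mode, object$covariates_in_model, light = TRUE,
                        pre = pre)
      eng$rho[median_index(eng$rho)]
    }, numeric(1))
  })
  rho_med <- object$rho[object$median]
  p <- mean(!is.na(rho_null) & rho_null >= rho_med)
  structure(list(rho_null = rho_null, rho_median = rho_med, p = p,
                 n_perm = n_perm), class = "cpm_perm")
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat(sprintf("Permutation test: rho_median = %.4f over %d permutations, p %s\n",
              x$rho_median, x$n_perm,
              if (x$p == 0) format_perm_p(x$p, x$n_perm)
              else paste("=", format_perm_p(x$p, x$n_perm))))
  invisible(x)
}
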