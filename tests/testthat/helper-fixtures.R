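# Shared fixture builders and independent oracles. Oracles deliberately use
# naive definitional computations (explicit loops, lm residuals) so they are
# independent of the package's vectorised implementations.

small_cohort <- function(n_per_sex = 30, nodes = 30, planted = NULL,
                         seed = 1, ...) {
  a <- synthetic_atlas(nodes)
  simulate_cohort(a, n_female = n_per_sex, n_male = n_per_sex,
                  planted_female = planted, seed = seed, ...)
}

# A minimal object that quacks like a fitted cpm for consensus/intranet
# code: fold_models[[iteration]][[fold]] = list(positive=, negative=).
fake_fit <- function(fold_models, n_edges, k, atlas = NULL) {
  structure(list(x = matrix(0, 2, n_edges), k = k,
                 n_iterations = length(fold_models),
                 fold_models = fold_models, atlas = atlas),
            class = "cpm")
}

# Brute-force partial-correlation selection: residualize edge and score on
# the covariates with lm(), correlate residuals, t-transform p-value.
oracle_select <- function(x, y, covariates = NULL, alpha = 0.01) {
  n <- length(y)
  d0 <- if (is.null(covariates)) data.frame(y = y)
        else data.frame(y = y, covariates)
  yr <- stats::resid(stats::lm(y ~ ., data = d0))
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  r <- p <- numeric(ncol(x))
  for (e in seq_len(ncol(x))) {
    de <- if (is.null(covariates)) data.frame(v = x[, e])
          else data.frame(v = x[, e], covariates)
    if (stats::sd(x[, e]) == 0) { r[e] <- 0; p[e] <- 1; next }
    xr <- stats::resid(stats::lm(v ~ ., data = de))
    r[e] <- stats::cor(xr, yr)
    df <- n - 2 - ncov
    tt <- r[e] * sqrt(df / (1 - r[e]^2))
    p[e] <- 2 * stats::pt(-abs(tt), df)
  }
  list(positive = which(p < alpha & r > 0),
       negative = which(p < alpha & r < 0), stat = r, p = p)
}

# Quadratic-time BH step-up from the definition.
oracle_bh <- function(p, m = length(p)) {
  out <- numeric(length(p))
  ord <- order(p)
  for (pos in seq_along(p)) {
    i <- which(ord == pos)  # rank of this p
    cand <- vapply(seq(i, length(p)), function(j) p[ord[j]] * m / j,
                   numeric(1))
    out[pos] <- min(1, min(cand))
  }
  out
}

# Definitional Spearman: average ranks, then textbook Pearson.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force consensus recount from stored per-fold selections.
oracle_consensus <- function(fold_models, n_edges, min_folds, frac) {
  n_it <- length(fold_models)
  res <- list()
  for (sgn in c("positive", "negative")) {
    fold_count <- integer(n_edges); qual <- integer(n_edges)
    for (e in seq_len(n_edges)) {
      for (it in fold_models) {
        hits <- sum(vapply(it, function(f) e %in% f[[sgn]], logical(1)))
        fold_count[e] <- fold_count[e] + hits
        if (hits >= min_folds) qual[e] <- qual[e] + 1L
      }
    }
    res[[sgn]] <- list(fold_count = fold_count, qual = qual,
                       sig = qual >= frac * n_it)
  }
  res
}

# Edge-enumeration association ratio over a full weight matrix.
oracle_assoc_ratio <- function(w, labels, network) {
  nodes <- which(labels == network)
  num <- 0; den <- 0
  for (i in seq_len(nrow(w) - 1)) for (j in (i + 1):nrow(w)) {
    within <- (i %in% nodes) && (j %in% nodes)
    boundary <- xor(i %in% nodes, j %in% nodes)
    if (within) num <- num + w[i, j]
    if (within || boundary) den <- den + w[i, j]
  }
  num / den
}
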