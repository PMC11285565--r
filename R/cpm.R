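#' Covariate-adjusted edge-wise feature selection
#'
#' For every edge, computes the partial Pearson correlation between edge
#' weight and score controlling for the covariates (both are residualized
#' on the covariates by least squares, then the residuals are correlated).
#' Significance uses the t-transform of the partial correlation with
#' `df = n - 2 - n_covariates`; edges with two-sided p below `alpha` enter
#' the positive or negative set according to the sign of the partial
#' correlation. With no covariates this reduces to plain Pearson
#' edge-score selection.
#'
#' Constant edges get a partial correlation of 0 (p = 1) and are never
#' selected. A constant score vector is an error.
#'
#' @param x Subjects x edges numeric matrix (training set).
#' @param y Numeric score vector.
#' @param covariates Optional subjects x c matrix/data frame of nuisance
#'   covariates.
#' @param alpha Two-sided selection threshold (default 0.01).
#' @return Object of class `cpm_selection`: list with `positive` and
#'   `negative` (disjoint integer edge-index sets), `stat` (partial r per
#'   edge), `p` (two-sided p per edge), `df`, `n`.
#' @export
select_edges <- function(x, y, covariates = NULL, alpha = 0.01) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must match nrow(x)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (stats::var(y) == 0) stop("score vector is constant in the training set")
  Z <- if (is.null(covariates) || NCOL(covariates) == 0L)
    matrix(1, n, 1L) else cbind(1, as.matrix(covariates))
  ncov <- ncol(Z) - 1L
  if (n < ncov + 4L)
    stop("need at least ", ncov + 4L, " training subjects for ", ncov,
         " covariate(s)")
  # project out the covariate span via the thin Q factor (BLAS-level ops;
  # equivalent to least-squares residualization)
  Q <- qr.Q(qr(Z))
  yr <- y - Q %*% crossprod(Q, y)
  xr <- x - Q %*% crossprod(Q, x)
  sy2 <- sum(yr^2)
  sx2 <- unname(colSums(xr^2))
  const <- sx2 < .Machine$double.eps * n
  r <- as.numeric(crossprod(xr, yr)) / sqrt(pmax(sx2, .Machine$double.xmin) * sy2)
  r <- pmin(pmax(r, -1), 1)
  r[const] <- 0
  df <- n - 2L - ncov
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[const] <- 1
  structure(list(positive = which(p < alpha & r > 0),
                 negative = which(p < alpha & r < 0),
                 stat = r, p = p, df = df, n = n, alpha = alpha),
            class = "cpm_selection")
}

#' Single-subject summed connectivity
#'
#' Collapses the selected edges of one or more subjects into one scalar
#' per subject: in `"combined"` mode the sum of positive-set edge weights
#' minus the sum of negative-set weights; `"positive"` / `"negative"`
#' return the respective sums alone. An empty set contributes 0.
#'
#' @param x Edge vector (one subject) or subjects x edges matrix.
#' @param selection A `cpm_selection` (or list with `positive`/`negative`
#'   integer elements).
#' @param mode `"combined"`, `"positive"` or `"negative"`.
#' @return Scalar (vector input) or one value per row (matrix input).
#' @export
summed_connectivity <- function(x, selection,
                                mode = c("combined", "positive", "negative")) {
  mode <- match.arg(mode)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  part <- function(idx) {
    if (!length(idx)) return(rep(0, nrow(x)))
    rowSums(x[, idx, drop = FALSE])
  }
  out <- switch(mode,
    combined = part(selection$positive) - part(selection$negative),
    positive = part(selection$positive),
    negative = part(selection$negative))
  out <- unname(out)
  if (nrow(x) == 1L) out[1L] else out
}

# OLS of score on summed connectivity for one training fold; degenerate
# folds (no selected edges for the mode, or zero variance of the sum)
# fall back to predicting the training-mean score.
fit_fold <- function(s, y, C = NULL, covariates_in_model = FALSE,
                     empty_selection = FALSE) {
  ybar <- mean(y)
  if (empty_selection || stats::var(s) == 0)
    return(list(slope = 0, intercept = ybar, extra = NULL,
                degenerate = TRUE, ybar = ybar))
  if (covariates_in_model && !is.null(C) && ncol(C) > 0L) {
    D <- cbind(1, s, C)
    cf <- stats::lm.fit(D, y)$coefficients
    cf[is.na(cf)] <- 0
    return(list(slope = cf[2L], intercept = cf[1L], extra = cf[-(1:2)],
                degenerate = FALSE, ybar = ybar))
  }
  b <- stats::cov(s, y) / stats::var(s)
  list(slope = b, intercept = ybar - b * mean(s), extra = NULL,
       degenerate = FALSE, ybar = ybar)
}

predict_fold <- function(model, s, C = NULL) {
  if (model$degenerate) return(rep(model$ybar, length(s)))
  out <- model$intercept + model$slope * s
  if (!is.null(model$extra) && length(model$extra))
    out <- out + as.numeric(C %*% model$extra)
  out
}

quiet_spearman <- function(x, y) suppressWarnings(spearman_rho(x, y))

# Precompute fold-independent cross-moments so that each fold's partial
# correlations can be obtained by subtracting the test rows' contribution
# (exact algebraic identity with residualization on the training rows).
# Covariates are standardized (same residual span) for conditioning.
cpm_precompute <- function(X, C) {
  n <- nrow(X)
  if (ncol(C)) {
    mu <- colMeans(C)
    sdv <- apply(C, 2L, stats::sd)
    keep <- sdv > 0
    Cs <- sweep(C[, keep, drop = FALSE], 2L, mu[keep], `-`)
    Cs <- sweep(Cs, 2L, sdv[keep], `/`)
    Z <- cbind(1, Cs)
  } else Z <- matrix(1, n, 1L)
  list(X = X, Z = Z, ncov = ncol(Z) - 1L,
       ZtZ = crossprod(Z), ZtX = crossprod(Z, X), cs2 = colSums(X^2))
}

cpm_precompute_y <- function(pre, y) {
  list(y = y, ytX = as.numeric(crossprod(pre$X, y)),
       Zty = as.numeric(crossprod(pre$Z, y)), yty = sum(y^2))
}

# Fold-level edge selection from sufficient statistics; equals
# select_edges() on the training subset (tested). Falls back to the
# direct path if the fold's covariate cross-product is singular.
select_fold_fast <- function(pre, ys, te, alpha) {
  Zte <- pre$Z[te, , drop = FALSE]
  Xte <- pre$X[te, , drop = FALSE]
  yte <- ys$y[te]
  n_tr <- nrow(pre$X) - length(te)
  A <- pre$ZtZ - crossprod(Zte)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    tr <- setdiff(seq_len(nrow(pre$X)), te)
    return(select_edges(pre$X[tr, , drop = FALSE], ys$y[tr],
                        if (pre$ncov) pre$Z[tr, -1L, drop = FALSE] else NULL,
                        alpha))
  }
  ZtX <- pre$ZtX - crossprod(Zte, Xte)
  cs2 <- unname(pre$cs2 - colSums(Xte^2))
  b_y <- ys$Zty - as.numeric(crossprod(Zte, yte))
  ytX <- ys$ytX - as.numeric(crossprod(Xte, yte))
  yty <- ys$yty - sum(yte^2)
  beta_y <- backsolve(R, backsolve(R, b_y, transpose = TRUE))
  beta_x <- backsolve(R, backsolve(R, ZtX, transpose = TRUE))
  sxy <- ytX - as.numeric(crossprod(ZtX, beta_y))
  sx2 <- pmax(cs2 - colSums(ZtX * beta_x), 0)
  sy2 <- max(yty - sum(b_y * beta_y), 0)
  if (sy2 <= ys$yty * 1e-12)
    stop("score vector is constant in the training set")
  const <- sx2 <= pmax(cs2, .Machine$double.xmin) * 1e-10
  r <- sxy / sqrt(pmax(sx2, .Machine$double.xmin) * sy2)
  r <- pmin(pmax(r, -1), 1)
  r[const] <- 0
  df <- n_tr - 2L - pre$ncov
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[const] <- 1
  structure(list(positive = which(p < alpha & r > 0),
                 negative = which(p < alpha & r < 0),
                 stat = r, p = p, df = df, n = n_tr, alpha = alpha),
            class = "cpm_selection")
}

# Full CV-iteration engine. Assumes the RNG state is already set by the
# caller. light = TRUE computes only per-iteration performance (used by
# the permutation test).
cpm_engine <- function(X, y, C, k, n_iterations, alpha, mode,
                       covariates_in_model, light = FALSE,
                       pre = cpm_precompute(X, C)) {
  n <- length(y)
  ys <- cpm_precompute_y(pre, y)
  rho <- numeric(n_iterations)
  rmse_v <- numeric(n_iterations)
  preds <- if (!light) matrix(NA_real_, n, n_iterations) else NULL
  folds_m <- if (!light) matrix(NA_integer_, n, n_iterations) else NULL
  fold_models <- if (!light) vector("list", n_iterations) else NULL
  for (it in seq_len(n_iterations)) {
    folds <- sample(rep(seq_len(k), length.out = n))
    p_it <- numeric(n)
    recs <- if (!light) vector("list", k) else NULL
    for (f in seq_len(k)) {
      tr <- folds != f
      sel <- select_fold_fast(pre, ys, which(!tr), alpha)
      empty <- switch(mode,
        combined = !length(sel$positive) && !length(sel$negative),
        positive = !length(sel$positive),
        negative = !length(sel$negative))
      s_all <- summed_connectivity(X, sel, mode)
      model <- fit_fold(s_all[tr], y[tr],
                        C = if (ncol(C)) C[tr, , drop = FALSE] else NULL,
                        covariates_in_model = covariates_in_model,
                        empty_selection = empty)
      p_it[!tr] <- predict_fold(model, s_all[!tr],
                                if (ncol(C)) C[!tr, , drop = FALSE] else NULL)
      if (!light)
        recs[[f]] <- list(positive = sel$positive, negative = sel$negative,
                          stat_positive = sel$stat[sel$positive],
                          stat_negative = sel$stat[sel$negative],
                          p_positive = sel$p[sel$positive],
                          p_negative = sel$p[sel$negative],
                          slope = model$slope, intercept = model$intercept,
                          extra = model$extra, degenerate = model$degenerate,
                          ybar = model$ybar)
    }
    rho[it] <- quiet_spearman(p_it, y)
    rmse_v[it] <- rmse(p_it, y)
    if (!light) {
      preds[, it] <- p_it
      folds_m[, it] <- folds
      fold_models[[it]] <- recs
    }
  }
  list(rho = rho, rmse = rmse_v, predictions = preds, folds = folds_m,
       fold_models = fold_models)
}

resolve_cpm_data <- function(data, edges, scan) {
  if (inherits(data, "cpm_cohort")) {
    if (is.null(scan)) scan <- names(data$edges)[1L]
    if (!scan %in% names(data$edges)) stop("unknown scan label: ", scan)
    list(df = data$subjects, X = data$edges[[scan]], atlas = data$atlas,
         scan = scan)
  } else {
    if (is.null(edges)) stop("supply `edges` when `data` is a plain data frame")
    list(df = as.data.frame(data), X = as.matrix(edges),
         atlas = attr(edges, "atlas"), scan = scan)
  }
}

#' Fit a connectome-based predictive model
#'
#' The full CPM procedure: over `n_iterations` random k-fold partitions,
#' each training set undergoes covariate-adjusted edge selection
#' ([select_edges]) at threshold `alpha`; the selected edges are collapsed
#' per subject into a summed connectivity value ([summed_connectivity])
#' and the score is regressed on it by ordinary least squares; the fold
#' model then predicts the held-out subjects. Every subject is predicted
#' exactly once per iteration; per-iteration performance is the Spearman
#' correlation (and RMSE) between out-of-fold predictions and observed
#' scores, and the ensemble is represented by its median-performing
#' iteration ([median_model]).
#'
#' The left side of `formula` names the score column in the subject
#' table; the right side names the nuisance covariates entered into the
#' edge selection (e.g. `ravlt_ir ~ ffd_FACENAME * age` for motion, age
#' and their interaction). Use `~ 1` for no covariates. By default the
#' covariates act only through the partial-correlation selection; set
#' `covariates_in_model = TRUE` to also enter them into the fold-level
#' prediction regression.
#'
#' @param formula `score ~ covariates`, resolved in the subject table.
#' @param data A `cpm_cohort` (subject table + edge matrices) or a plain
#'   data frame (then supply `edges`).
#' @param edges Subjects x edges matrix when `data` is a data frame.
#' @param scan Scan label selecting the edge matrix of a cohort; default
#'   the first.
#' @param subset Optional logical expression over subject-table columns
#'   (e.g. `sex == "F"`) restricting the fitted group.
#' @param k Number of CV folds (default 5).
#' @param n_iterations Number of random-partition iterations (default
#'   1000).
#' @param alpha Edge-selection threshold (default 0.01).
#' @param mode Summed-connectivity mode: `"combined"` (positive sum minus
#'   negative sum; default), `"positive"` or `"negative"`.
#' @param covariates_in_model Also include covariates in the fold-level
#'   regression (default FALSE).
#' @param seed RNG seed; the whole fit is reproducible given
#'   (data, config, seed).
#' @return Object of class `cpm` with, among others: `rho` and `rmse`
#'   (per-iteration out-of-fold performance), `median` (index of the
#'   median-performing iteration), `predictions` (subjects x iterations
#'   out-of-fold predictions), `fold_models` (per-iteration, per-fold
#'   edge selections and linear coefficients), and the training data
#'   needed by [predict.cpm] and [cpm_permute].
#' @seealso [predict.cpm], [cpm_transfer], [cpm_permute],
#'   [consensus_edges]
#' @examples
#' a <- synthetic_atlas(30)
#' co <- simulate_cohort(a, n_female = 30, n_male = 30,
#'                       planted_female = planted_edges(a, "DMN", 3),
#'                       seed = 2)
#' fit <- cpm(ravlt_ir ~ ffd_FACENAME * age, co, n_iterations = 10, seed = 3)
#' summary(fit)
#' @export
cpm <- function(formula, data, edges = NULL, scan = NULL, subset = NULL,
                k = 5L, n_iterations = 1000L, alpha = 0.01,
                mode = c("combined", "positive", "negative"),
                covariates_in_model = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  n_iterations <- as.integer(n_iterations)
  if (k < 2L) stop("k must be at least 2")
  if (n_iterations < 1L) stop("n_iterations must be positive")
  rd <- resolve_cpm_data(data, edges, scan)
  df <- rd$df; X <- rd$X
  if (nrow(df) != nrow(X)) stop("subject table and edge matrix disagree on n")

  e <- substitute(subset)
  if (!is.null(e)) {
    keep <- eval(e, df, parent.frame())
    if (is.logical(keep)) keep <- which(keep & !is.na(keep))
    df <- df[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }

  mf <- stats::model.frame(formula, df)
  y <- unname(stats::model.response(mf))
  if (is.null(y)) stop("formula must have a response (the score)")
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  C <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  n <- length(y)
  if (n < k) stop("fewer subjects (", n, ") than folds (", k, ")")

  eng <- with_seed(seed, cpm_engine(X, y, C, k, n_iterations, alpha, mode,
                                    covariates_in_model))
  med <- median_index(eng$rho)
  structure(list(
    call = match.call(), formula = formula,
    score = all.vars(formula[[2L]])[1L],
    y = y, covariates = C, x = X,
    subjects = df, atlas = rd$atlas, scan = rd$scan,
    n = n, k = k, n_iterations = n_iterations, alpha = alpha, mode = mode,
    covariates_in_model = covariates_in_model, seed = as.integer(seed),
    rho = eng$rho, rmse = eng$rmse,
    predictions = eng$predictions, folds = eng$folds,
    fold_models = eng$fold_models,
    median = med), class = "cpm")
}

# Rank iterations by out-of-fold Spearman rho and return the index of the
# lower median (rank ceiling(n/2)); ties broken by lower iteration index,
# NA performance (degenerate) sorts lowest.
median_index <- function(rho) {
  r <- rho
  r[is.na(r)] <- -Inf
  ord <- order(r, seq_along(r))
  ord[ceiling(length(r) / 2)]
}

#' Median-performing iteration of a CPM ensemble
#'
#' Iterations are ranked by out-of-fold Spearman rho; the iteration at
#' rank ceiling(n/2) (the lower median for even counts) represents the
#' ensemble. Ties are broken by lower iteration index; iterations with
#' undefined performance rank lowest.
#'
#' @param object A fitted `cpm` object.
#' @return List with the median iteration's index, performance, fold
#'   assignment, per-fold models and out-of-fold predictions.
#' @export
median_model <- function(object) {
  stopifnot(inherits(object, "cpm"))
  i <- object$median
  list(iteration = i, rho = object$rho[i], rmse = object$rmse[i],
       folds = object$folds[, i], fold_models = object$fold_models[[i]],
       predictions = object$predictions[, i])
}

#' @export
print.cpm <- function(x, ...) {
  cat("Connectome-based predictive model\n")
  cat("  score:", x$score, if (!is.null(x$scan)) paste0("(scan ", x$scan, ")"),
      "\n")
  cat(sprintf("  n = %d subjects, %d edges, %d-fold CV, %d iteration(s), alpha = %g, mode = %s\n",
              x$n, ncol(x$x), x$k, x$n_iterations, x$alpha, x$mode))
  cat(sprintf("  median model: iteration %d, Spearman rho = %.4f, RMSE = %.4f\n",
              x$median, x$rho[x$median], x$rmse[x$median]))
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  sel_sizes <- vapply(object$fold_models, function(it)
    mean(vapply(it, function(f) length(f$positive) + length(f$negative),
                numeric(1))), numeric(1))
  degen <- sum(vapply(object$fold_models, function(it)
    sum(vapply(it, function(f) f$degenerate, logical(1))), numeric(1)))
  out <- list(score = object$score, scan = object$scan, n = object$n,
              k = object$k, n_iterations = object$n_iterations,
              alpha = object$alpha, mode = object$mode,
              rho_median = object$rho[object$median],
              rmse_median = object$rmse[object$median],
              rho_quantiles = stats::quantile(object$rho,
                                              c(0.025, 0.25, 0.5, 0.75, 0.975),
                                              na.rm = TRUE),
              mean_selected = mean(sel_sizes),
              degenerate_folds = degen)
  class(out) <- "summary.cpm"
  out
}

#' @export
print.summary.cpm <- function(x, ...) {
  cat("CPM of", x$score, if (!is.null(x$scan)) paste0("(scan ", x$scan, ")"),
      "\n")
  cat(sprintf("  n = %d, %d-fold CV x %d iterations, alpha = %g, mode = %s\n",
              x$n, x$k, x$n_iterations, x$alpha, x$mode))
  cat(sprintf("  median-model Spearman rho = %.4f, RMSE = %.4f\n",
              x$rho_median, x$rmse_median))
  cat("  rho quantiles across iterations:\n")
  print(round(x$rho_quantiles, 4))
  cat(sprintf("  mean selected edges per fold: %.1f; degenerate folds: %d\n",
              x$mean_selected, x$degenerate_folds))
  invisible(x)
}

#' @export
coef.cpm <- function(object, iteration = object$median, ...) {
  fm <- object$fold_models[[iteration]]
  t(vapply(fm, function(f) c(intercept = f$intercept, slope = f$slope),
           numeric(2)))
}

#' @export
fitted.cpm <- function(object, ...) object$predictions[, object$median]

#' @export
residuals.cpm <- function(object, ...)
  object$y - object$predictions[, object$median]

#' Predict scores for new subjects from a fitted CPM
#'
#' Applies the fold models trained inside the source group to new
#' subjects' edge vectors: for each iteration, each of the k fold models
#' produces a prediction for every new subject and the k predictions are
#' averaged. This is the mechanism behind cross-group model transfer
#' (see [cpm_transfer]). With `newdata` omitted, returns the
#' cross-validated out-of-fold predictions of the median iteration.
#'
#' @param object A fitted `cpm`.
#' @param newdata New subjects' edge matrix (subjects x edges), or a
#'   `cpm_cohort`.
#' @param scan Scan label when `newdata` is a cohort; defaults to the
#'   fitted scan.
#' @param newcovariates Covariate matrix for the new subjects, only used
#'   when the model was fitted with `covariates_in_model = TRUE`.
#' @param iterations `"median"` (default) for a vector of predictions
#'   from the median iteration, or `"all"` for a subjects x iterations
#'   matrix.
#' @param ... Unused.
#' @return Numeric vector or matrix of predicted scores.
#' @export
predict.cpm <- function(object, newdata = NULL, scan = NULL,
                        newcovariates = NULL,
                        iterations = c("median", "all"), ...) {
  iterations <- match.arg(iterations)
  if (is.null(newdata)) {
    return(if (iterations == "median") fitted(object) else object$predictions)
  }
  if (inherits(newdata, "cpm_cohort")) {
    if (is.null(scan)) scan <- object$scan
    Xn <- newdata$edges[[scan %||% names(newdata$edges)[1L]]]
  } else Xn <- as.matrix(newdata)
  if (ncol(Xn) != ncol(object$x))
    stop("new edge matrix has ", ncol(Xn), " edges; model expects ",
         ncol(object$x))
  if (nrow(Xn) == 0L) stop("no subjects to predict")
  its <- if (iterations == "median") object$median
         else seq_len(object$n_iterations)
  out <- matrix(NA_real_, nrow(Xn), length(its))
  for (ii in seq_along(its)) {
    fm <- object$fold_models[[its[ii]]]
    acc <- 0
    for (f in fm) {
      s <- summed_connectivity(Xn, f, object$mode)
      acc <- acc + predict_fold(f, s, newcovariates)
    }
    out[, ii] <- acc / length(fm)
  }
  if (iterations == "median") out[, 1L] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.cpm <- function(x, ...) {
  obs <- x$y
  pred <- fitted(x)
  graphics::plot(pred, obs, xlab = "Predicted score (out-of-fold)",
                 ylab = "Observed score",
                 main = sprintf("%s: median-model rho = %.3f",
                                x$score, x$rho[x$median]), ...)
  graphics::abline(stats::lm(obs ~ pred), lty = 2)
  invisible(x)
}

#' @export
simulate.cpm <- function(object, nsim = 1, seed = NULL, ...) {
  # parametric draws around the median-model predictions using the
  # residual SD of the out-of-fold fit
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sdr <- stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sdr)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Cross-group transfer of a fitted CPM
#'
#' Evaluates a model trained inside one group (e.g. female subjects) on
#' the subjects of another (e.g. male subjects): per iteration, the k
#' fold models each predict all target subjects and the fold predictions
#' are averaged before scoring against the target group's observed
#' scores. Returns the full performance distribution over iterations.
#'
#' @param object A fitted `cpm` (the source-group model).
#' @param data Target group: a `cpm_cohort` or data frame.
#' @param edges Target edge matrix when `data` is a data frame.
#' @param scan Scan label (cohort input); defaults to the fitted scan.
#' @param subset Optional logical expression selecting the target group
#'   within `data` (e.g. `sex == "M"`).
#' @return Object of class `cpm_transfer`: per-iteration `rho` and
#'   `rmse` on the target group, the median-iteration index and its
#'   predictions.
#' @export
cpm_transfer <- function(object, data, edges = NULL, scan = NULL,
                         subset = NULL) {
  stopifnot(inherits(object, "cpm"))
  rd <- resolve_cpm_data(data, edges, scan %||% object$scan)
  df <- rd$df; Xn <- rd$X
  e <- substitute(subset)
  if (!is.null(e)) {
    keep <- eval(e, df, parent.frame())
    if (is.logical(keep)) keep <- which(keep & !is.na(keep))
    df <- df[keep, , drop = FALSE]
    Xn <- Xn[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("target group is empty")
  yn <- df[[object$score]]
  if (is.null(yn)) stop("target data lacks score column ", object$score)
  P <- predict(object, Xn, iterations = "all")
  rho <- apply(P, 2L, quiet_spearman, y = yn)
  rmse_v <- apply(P, 2L, rmse, observed = yn)
  med <- median_index(rho)
  structure(list(rho = rho, rmse = rmse_v, median = med,
                 predictions = P[, med], observed = yn,
                 source_score = object$score, n_target = nrow(df)),
            class = "cpm_transfer")
}

#' @export
print.cpm_transfer <- function(x, ...) {
  cat("CPM transfer to", x$n_target, "target subjects\n")
  cat(sprintf("  median transfer rho = %.4f, RMSE = %.4f (over %d iterations)\n",
              x$rho[x$median], x$rmse[x$median], length(x$rho)))
  invisible(x)
}
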