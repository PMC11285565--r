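test_that("edge selection recovers exact and confounded relationships", {
  set.seed(1)
  n <- 40
  y <- rnorm(n)
  # one edge exactly equal to the score: partial r = 1, selected positive
  x <- cbind(y, matrix(rnorm(n * 4), n))
  sel <- select_edges(x, y)
  expect_true(1 %in% sel$positive)
  expect_equal(sel$stat[1], 1)
  # an edge that IS the covariate is fully removed by partialling
  cv <- rnorm(n)
  y2 <- rnorm(n)
  x2 <- cbind(cv, matrix(rnorm(n * 4), n))
  sel2 <- select_edges(x2, y2, covariates = cbind(cv), alpha = 0.05)
  expect_false(1 %in% c(sel2$positive, sel2$negative))
  expect_lt(abs(sel2$stat[1]), 1e-6)
})

test_that("edge selection handles degenerate inputs per contract", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  expect_error(select_edges(x, rep(1, 20)), "constant")
  xc <- x; xc[, 2] <- 5
  sel <- select_edges(xc, rnorm(20), alpha = 0.5)
  expect_equal(sel$stat[2], 0)
  expect_equal(sel$p[2], 1)
  expect_false(2 %in% c(sel$positive, sel$negative))
  expect_error(select_edges(x, rnorm(20), alpha = 0), "alpha")
})

test_that("selection equals the residualization oracle, and no-covariate selection is plain Pearson", {
  set.seed(3)
  n <- 50
  x <- matrix(rnorm(n * 100), n)
  y <- rnorm(n) + 0.5 * x[, 1]
  cv <- data.frame(a = rnorm(n), b = runif(n, 36, 100))
  sel <- select_edges(x, y, cv, alpha = 0.05)
  ora <- oracle_select(x, y, cv, alpha = 0.05)
  expect_equal(sel$positive, ora$positive)
  expect_equal(sel$negative, ora$negative)
  expect_equal(sel$stat, ora$stat, tolerance = 1e-10)
  expect_equal(sel$p, ora$p, tolerance = 1e-10)
  # empty covariate list reduces to plain edge-score Pearson correlation
  sel0 <- select_edges(x, y, alpha = 0.05)
  expect_equal(sel0$stat, as.numeric(cor(x, y)), tolerance = 1e-12)
})

test_that("summed connectivity follows the signed-sum definition", {
  sel <- list(positive = 1L, negative = 2L)
  x <- c(0.5, 0.2, 9)
  expect_equal(summed_connectivity(x, sel, "combined"), 0.3)
  expect_equal(summed_connectivity(x, sel, "positive"), 0.5)
  expect_equal(summed_connectivity(x, sel, "negative"), 0.2)
  # empty negative set: combined equals positive-only
  selp <- list(positive = c(1L, 3L), negative = integer(0))
  expect_equal(summed_connectivity(x, selp, "combined"),
               summed_connectivity(x, selp, "positive"))
  expect_equal(summed_connectivity(rep(0, 3), sel, "combined"), 0)
  # matrix input gives one value per subject
  X <- rbind(x, 2 * x)
  expect_equal(summed_connectivity(X, sel, "combined"), c(0.3, 0.6))
})

test_that("fold models are exact least squares with mean fallback", {
  # two-point line: (0,1),(1,3) -> slope 2, intercept 1; predict(2) = 5
  m <- cpmr:::fit_fold(c(0, 1), c(1, 3))
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_equal(cpmr:::predict_fold(m, 2), 5)
  # constant y -> zero slope, constant prediction
  mc <- cpmr:::fit_fold(c(0, 1, 2), c(4, 4, 4))
  expect_equal(mc$slope, 0)
  expect_equal(cpmr:::predict_fold(mc, 10), 4)
  # degenerate (empty selection / zero-variance sum) -> training mean
  md <- cpmr:::fit_fold(rep(1, 5), 1:5, empty_selection = TRUE)
  expect_true(md$degenerate)
  expect_equal(cpmr:::predict_fold(md, c(0, 9)), c(3, 3))
  # closed-form OLS oracle on a larger fold
  set.seed(4)
  s <- rnorm(200); y <- 1.5 * s + rnorm(200)
  mo <- cpmr:::fit_fold(s, y)
  co <- unname(coef(lm(y ~ s)))
  expect_equal(c(mo$intercept, mo$slope), co, tolerance = 1e-12)
})

test_that("a full fit is deterministic and predicts every subject once", {
  co <- small_cohort(n_per_sex = 25, nodes = 20, seed = 6)
  f1 <- cpm(ravlt_l ~ ffd_FACENAME * age, co, n_iterations = 3, seed = 42)
  f2 <- cpm(ravlt_l ~ ffd_FACENAME * age, co, n_iterations = 3, seed = 42)
  expect_identical(f1$rho, f2$rho)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$folds, f2$folds)
  expect_identical(f1$fold_models, f2$fold_models)
  # every subject out-of-fold predicted once per iteration
  expect_false(anyNA(f1$predictions))
  # fold sizes differ by at most one
  sz <- apply(f1$folds, 2, function(f) diff(range(tabulate(f, 5))))
  expect_true(all(sz <= 1))
  # positive/negative sets disjoint in every fold
  for (it in f1$fold_models) for (f in it)
    expect_length(intersect(f$positive, f$negative), 0)
})

test_that("median-model selection uses the lower median with index ties", {
  expect_equal(cpmr:::median_index(c(0.1, 0.5, 0.3)), 3L)
  expect_equal(cpmr:::median_index(0.7), 1L)
  # even count: lower median (rank 2 of 4 is the 0.2 at index 4)
  expect_equal(cpmr:::median_index(c(0.4, 0.1, 0.3, 0.2)), 4L)
  # ties ordered by iteration index: rank 2 of four equal values
  expect_equal(cpmr:::median_index(c(0.2, 0.2, 0.2, 0.2)), 2L)
  # NA (degenerate) ranks lowest
  expect_equal(cpmr:::median_index(c(NA, 0.5, 0.1)), 3L)
  # sorting oracle on random vectors
  set.seed(7)
  for (rep in 1:20) {
    v <- round(rnorm(sample(3:30, 1)), 2)
    i <- cpmr:::median_index(v)
    ord <- order(v, seq_along(v))
    expect_equal(i, ord[ceiling(length(v) / 2)])
  }
})

test_that("median_model exposes the representative iteration", {
  co <- small_cohort(n_per_sex = 20, nodes = 20, seed = 8)
  fit <- cpm(fn_tr ~ age, co, n_iterations = 5, seed = 2)
  mm <- median_model(fit)
  expect_equal(mm$rho, sort(fit$rho)[3])
  expect_equal(mm$predictions, fit$predictions[, mm$iteration])
  expect_equal(fitted(fit), fit$predictions[, fit$median])
  expect_equal(residuals(fit), fit$y - fitted(fit))
})

test_that("null cohorts give near-zero out-of-fold correlation", {
  # Monte-Carlo across independent null cohorts (one iteration each)
  rho <- vapply(1:10, function(s) {
    co <- small_cohort(n_per_sex = 30, nodes = 20, seed = 100 + s)
    fit <- cpm(ravlt_l ~ ffd_FACENAME * age, co, n_iterations = 1,
               seed = 200 + s)
    fit$rho[1]
  }, numeric(1))
  se <- sd(rho) / sqrt(length(rho))
  expect_lt(abs(mean(rho)), 3 * se + 0.05)
})

test_that("planted signal is recovered and dominates the selections", {
  a <- synthetic_atlas(30)
  pf <- planted_edges(a, "DMN", 3, seed = 31)
  co <- simulate_cohort(a, n_female = 80, n_male = 0, planted_female = pf,
                        beta = 0.5, seed = 32)
  fit <- cpm(ravlt_l ~ ffd_FACENAME * age, co, n_iterations = 10, seed = 33)
  expect_gt(fit$rho[fit$median], 0.2)
  planted_idx <- co$truth$edge_female
  hits <- vapply(fit$fold_models, function(it)
    mean(vapply(it, function(f) all(planted_idx %in% f$positive),
                logical(1))), numeric(1))
  expect_gt(mean(hits), 0.8)
})

test_that("subset and formula interfaces drive the fitted group", {
  co <- small_cohort(n_per_sex = 20, nodes = 20, seed = 10)
  ff <- cpm(fn_tr ~ age, co, subset = sex == "F", n_iterations = 2, seed = 1)
  expect_equal(ff$n, 20L)
  expect_equal(ff$y, co$subjects$fn_tr[co$subjects$sex == "F"])
  # interaction expands into three covariate columns
  fi <- cpm(fn_tr ~ ffd_FACENAME * age, co, n_iterations = 1, seed = 1)
  expect_equal(ncol(fi$covariates), 3L)
  expect_error(cpm(fn_tr ~ age, co, k = 50, n_iterations = 1), "folds")
})

test_that("transfer applies fold models to all target subjects", {
  a <- synthetic_atlas(30)
  co <- simulate_cohort(a, n_female = 40, n_male = 40,
                        planted_female = planted_edges(a, "DMN", 3, seed = 1),
                        beta = 0.8, seed = 44)
  fit <- cpm(ravlt_l ~ ffd_FACENAME * age, co, subset = sex == "F",
             n_iterations = 4, seed = 45)
  # degenerate identity: target group = source group runs and correlates
  same <- cpm_transfer(fit, co, subset = sex == "F")
  expect_length(same$rho, 4)
  expect_equal(same$n_target, 40L)
  # prediction is the average of the k fold models
  P <- predict(fit, co$edges$FACENAME, iterations = "all")
  expect_equal(dim(P), c(80L, 4L))
  fm <- fit$fold_models[[1]]
  manual <- rowMeans(vapply(fm, function(f)
    cpmr:::predict_fold(f, summed_connectivity(co$edges$FACENAME, f,
                                               "combined")),
    numeric(80)))
  expect_equal(P[, 1], manual, tolerance = 1e-12)
  expect_error(predict(fit, co$edges$FACENAME[, 1:10]), "edges")
  expect_error(cpm_transfer(fit, co, subset = sex == "X"), "empty")
})
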