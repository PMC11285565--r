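test_that("atlas construction, lookup and file round trip", {
  a <- synthetic_atlas(268)
  expect_equal(n_nodes(a), 268L)
  expect_equal(levels(a$network), cpm_networks)
  expect_true(all(table(a$network) >= 2))
  expect_length(network_nodes(a, "DMN"), 27L)
  expect_error(network_nodes(a, "nope"), "unknown network")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(a, f)
  b <- read_atlas(f)
  expect_equal(as.character(b$network), as.character(a$network))
  expect_equal(levels(b$network), levels(a$network))
  expect_error(synthetic_atlas(15), "at least 2 nodes per network")
})

test_that("cohort generation is bit-reproducible and well-formed", {
  co1 <- small_cohort(seed = 5)
  co2 <- small_cohort(seed = 5)
  co3 <- small_cohort(seed = 6)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$edges, co2$edges)
  expect_false(identical(co1$edges, co3$edges))
  # reconstructed connectomes are symmetric with zero diagonal and finite
  m <- devectorize_edges(co1$edges$FACENAME[1, ], 30)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(0, 30))
  expect_true(all(is.finite(co1$edges$FACENAME)))
})

test_that("scores never leave their legal integer ranges", {
  # crank the score noise so the latent scale is stressed
  co <- small_cohort(n_per_sex = 150, nodes = 20, seed = 3, score_sd = 5)
  s <- co$subjects
  expect_true(all(s$fn_tr %in% 0:10))
  expect_true(all(s$ravlt_l %in% 0:75))
  expect_true(all(s$ravlt_ir %in% 0:15))
  expect_true(all(s$age >= 36 & s$age <= 100))
  expect_true(all(s[grep("^ffd_", names(s))] >= 0))
})

test_that("generator input contracts are enforced", {
  a <- synthetic_atlas(20)
  expect_error(simulate_cohort(a, planted_female = cbind(3, 25)),
               "out of atlas range")
  expect_error(simulate_cohort(a, planted_female = cbind(3, 3)),
               "self-loops")
  expect_error(simulate_cohort(a, planted_female = rbind(c(1, 2), c(2, 1))),
               "duplicate")
  expect_error(simulate_cohort(a, n_female = 0, n_male = 0), "positive")
})

test_that("noise-free planted edges track the score perfectly", {
  a <- synthetic_atlas(20)
  co <- simulate_cohort(a, n_female = 40, n_male = 0,
                        planted_female = cbind(1, 2), beta = 2,
                        edge_sd = 1e-8, motion_effect = 0, age_effect = 0,
                        seed = 8)
  r <- co$truth$realized$FACENAME$female
  expect_equal(r$cor_z, 1, tolerance = 1e-4)
})

test_that("null cohorts have calibrated edge-score correlations", {
  co <- simulate_cohort(synthetic_atlas(30), n_female = 100, n_male = 0,
                        seed = 13)
  X <- co$edges$FACENAME
  y <- co$subjects$ravlt_l
  n <- nrow(X)
  r <- as.numeric(cor(X, y))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), n - 2)
  rate <- mean(p < 0.01)
  tol <- 3 * sqrt(0.01 * 0.99 / length(p))
  expect_lt(abs(rate - 0.01), tol + 1e-12)
  expect_lt(abs(mean(r)), 0.02)
})

test_that("realized planted correlations match the linear-Gaussian closed form", {
  a <- synthetic_atlas(100)
  pf <- planted_edges(a, "DMN", 20, seed = 21)
  co <- simulate_cohort(a, n_female = 200, n_male = 200,
                        planted_female = pf, beta = 0.5,
                        motion_effect = 0, age_effect = 0, seed = 22)
  realized <- co$truth$realized$FACENAME$female
  analytic <- 0.5 / sqrt(0.5^2 + co$truth$edge_sd^2)
  expect_equal(mean(realized$cor_z), analytic, tolerance = 0.1)
  # male connectomes carry no signal on the female set
  Xm <- co$edges$FACENAME[co$subjects$sex == "M", co$truth$edge_female]
  expect_lt(max(abs(cor(Xm, co$truth$z[co$subjects$sex == "M"]))), 0.25)
})

test_that("motion exclusion removes strictly-above-threshold and missing", {
  d <- data.frame(id = c("s1", "s2", "s3"),
                  ffd_REST1_AP = c(0.1, 0.3, 0.31))
  out <- apply_motion_exclusion(d, threshold = 0.3)
  expect_equal(out$subjects$id, c("s1", "s2"))  # 0.3 itself is kept
  expect_equal(out$exclusions$id, "s3")
  expect_equal(out$exclusions$reason, "above-threshold")
  expect_equal(out$exclusions$scan, "REST1_AP")

  # empty table -> empty table, empty log
  e <- apply_motion_exclusion(d[0, , drop = FALSE])
  expect_equal(nrow(e$subjects), 0L)
  expect_equal(nrow(e$exclusions), 0L)

  # all below threshold -> identity filter
  ok <- apply_motion_exclusion(data.frame(id = "a", ffd_X = 0.05))
  expect_equal(nrow(ok$subjects), 1L)

  # missing motion on any scan excludes with its own reason
  dm <- data.frame(id = c("a", "b"), ffd_A = c(0.1, NA), ffd_B = c(0.4, 0.1))
  om <- apply_motion_exclusion(dm)
  expect_equal(nrow(om$subjects), 0L)
  expect_setequal(om$exclusions$reason, c("above-threshold", "missing-motion"))
})

test_that("cohort files round-trip through the plain-text layout", {
  co <- small_cohort(n_per_sex = 4, nodes = 20, seed = 9)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- read_cohort(d)
  expect_equal(back$subjects$id, co$subjects$id)
  expect_equal(back$subjects$ravlt_ir, co$subjects$ravlt_ir)
  expect_equal(back$edges$FACENAME, co$edges$FACENAME, tolerance = 1e-8)
  expect_equal(as.character(back$atlas$network),
               as.character(co$atlas$network))
  expect_equal(back$truth$z, co$truth$z, tolerance = 1e-12)
})
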