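# compact constructors for synthetic selection histories
sel_it <- function(k, pos = rep(list(integer(0)), k),
                   neg = rep(list(integer(0)), k))
  lapply(seq_len(k), function(f) list(positive = pos[[f]], negative = neg[[f]]))

test_that("the 2-of-5-folds-in-40%-of-iterations rule is applied verbatim", {
  # edge 1 selected positive in exactly 2 folds in 400 of 1000 iterations
  hit <- sel_it(5, pos = list(1L, 1L, integer(0), integer(0), integer(0)))
  miss <- sel_it(5)
  fm <- c(rep(list(hit), 400), rep(list(miss), 600))
  cns <- consensus_edges(fake_fit(fm, n_edges = 3, k = 5))
  expect_true(cns$significant_positive[1])
  expect_equal(cns$qualifying_positive[1], 400L)
  expect_equal(cns$fold_count_positive[1], 800L)
  # 399 qualifying iterations fail the >= 400 bar
  cns399 <- consensus_edges(fake_fit(c(rep(list(hit), 399),
                                       rep(list(miss), 601)),
                                     n_edges = 3, k = 5))
  expect_false(cns399$significant_positive[1])
  # selected in only 1 fold in every iteration: qualifying count stays 0
  one <- sel_it(5, pos = list(2L, integer(0), integer(0), integer(0),
                              integer(0)))
  cns1 <- consensus_edges(fake_fit(rep(list(one), 1000), n_edges = 3, k = 5))
  expect_equal(cns1$qualifying_positive[2], 0L)
  expect_false(cns1$significant_positive[2])
})

test_that("consensus counts equal a brute-force recount of the fold logs", {
  set.seed(12)
  for (r in 1:5) {
    k <- 3; n_it <- 10; E <- 20
    fm <- lapply(seq_len(n_it), function(i)
      lapply(seq_len(k), function(f) {
        pos <- sample(E, sample(0:4, 1))
        neg <- sample(setdiff(seq_len(E), pos), sample(0:4, 1))
        list(positive = as.integer(pos), negative = as.integer(neg))
      }))
    cns <- consensus_edges(fake_fit(fm, E, k), min_folds = 2,
                           iteration_frac = 0.4)
    ora <- oracle_consensus(fm, E, min_folds = 2, frac = 0.4)
    expect_equal(cns$fold_count_positive, ora$positive$fold_count)
    expect_equal(cns$fold_count_negative, ora$negative$fold_count)
    expect_equal(cns$qualifying_positive, ora$positive$qual)
    expect_equal(cns$qualifying_negative, ora$negative$qual)
    # flags equal before the both-sign resolution, which only removes
    both <- ora$positive$sig & ora$negative$sig
    expect_equal(cns$significant_positive | cns$significant_negative |
                   seq_len(E) %in% cns$tied_edges,
                 ora$positive$sig | ora$negative$sig)
    expect_false(any(cns$significant_positive & cns$significant_negative))
  }
})

test_that("both-sign conflicts resolve to the larger qualifying count", {
  k <- 2
  both_p <- sel_it(k, pos = list(1L, 1L))          # qualifies positive
  both_n <- sel_it(k, neg = list(1L, 1L))          # qualifies negative
  # 6 positive vs 4 negative qualifying iterations out of 10 (frac 0.4)
  fm <- c(rep(list(both_p), 6), rep(list(both_n), 4))
  cns <- consensus_edges(fake_fit(fm, 2, k), min_folds = 2,
                         iteration_frac = 0.4)
  expect_true(cns$significant_positive[1])
  expect_false(cns$significant_negative[1])
  # exact tie: excluded and logged
  fm2 <- c(rep(list(both_p), 5), rep(list(both_n), 5))
  cns2 <- consensus_edges(fake_fit(fm2, 2, k), min_folds = 2,
                          iteration_frac = 0.4)
  expect_false(cns2$significant_positive[1])
  expect_false(cns2$significant_negative[1])
  expect_equal(cns2$tied_edges, 1L)
})

test_that("raising the iteration fraction never adds significant edges", {
  set.seed(13)
  fm <- lapply(1:20, function(i)
    lapply(1:3, function(f)
      list(positive = as.integer(sample(10, sample(0:3, 1))),
           negative = integer(0))))
  ft <- fake_fit(fm, 10, 3)
  prev <- rep(TRUE, 10)
  for (frac in c(0.2, 0.4, 0.6, 0.8)) {
    sig <- consensus_edges(ft, min_folds = 2,
                           iteration_frac = frac)$significant_positive
    expect_true(all(!sig | prev))  # sig subset of prev
    prev <- sig
  }
})

test_that("inter-network summaries normalize by pair size and conserve counts", {
  # toy atlas: A has 3 nodes, B has 4
  at <- atlas(c("A", "A", "A", "B", "B", "B", "B"))
  N <- 7; E <- N * (N - 1) / 2
  # pick 3 A-B edges as significant positive
  ab <- cbind(c(1, 2, 3), c(4, 5, 6))
  sig <- logical(E); sig[edge_index(ab[, 1], ab[, 2], N)] <- TRUE
  cns <- structure(list(significant_positive = sig,
                        significant_negative = logical(E),
                        atlas = at), class = "cpm_consensus")
  s <- summarize_internetwork(cns)
  expect_equal(s$positive["A", "B"], 3 / 12)
  expect_equal(s$positive["B", "A"], 3 / 12)
  expect_equal(s$positive["A", "A"], 0)
  expect_true(all(s$negative == 0, na.rm = TRUE))
  # conservation: unnormalized counts over unique pairs = total significant
  cnt <- s$count_positive
  expect_equal(sum(cnt[upper.tri(cnt, diag = TRUE)]), sum(sig))

  # loop oracle on random consensus flags
  set.seed(14)
  labs <- sample(c("A", "B", "C"), 8, replace = TRUE, prob = c(.4, .4, .2))
  labs[1:6] <- rep(c("A", "B", "C"), 2)  # ensure >= 2 nodes each
  at2 <- atlas(labs)
  E2 <- 8 * 7 / 2
  sigr <- runif(E2) < 0.3
  cns2 <- structure(list(significant_positive = sigr,
                         significant_negative = logical(E2),
                         atlas = at2), class = "cpm_consensus")
  s2 <- summarize_internetwork(cns2)
  ep <- edge_pairs(8)
  for (na in unique(labs)) for (nb in unique(labs)) {
    hits <- 0; tot <- 0
    for (e in seq_len(E2)) {
      li <- labs[ep[e, 1]]; lj <- labs[ep[e, 2]]
      if ((li == na && lj == nb) || (li == nb && lj == na)) {
        tot <- tot + 1
        if (sigr[e]) hits <- hits + 1
      }
    }
    expect_equal(s2$count_positive[na, nb], hits)
    expect_equal(s2$positive[na, nb], hits / tot)
  }
})

test_that("difference maps are cellwise subtraction on a shared atlas", {
  at <- atlas(rep(c("A", "B"), each = 3))
  E <- 15
  mk <- function(sig) structure(list(significant_positive = sig,
                                     significant_negative = logical(E),
                                     atlas = at), class = "cpm_consensus")
  set.seed(15)
  sa <- runif(E) < 0.4; sb <- runif(E) < 0.4
  fa <- summarize_internetwork(mk(sa)); fb <- summarize_internetwork(mk(sb))
  d <- difference_map(fa, fb)
  expect_equal(d$positive, fa$positive - fb$positive)
  expect_equal(difference_map(fa, fa)$positive,
               matrix(0, 2, 2, dimnames = dimnames(fa$positive)))
  zero <- summarize_internetwork(mk(logical(E)))
  expect_equal(difference_map(fa, zero)$positive, fa$positive)
  other <- summarize_internetwork(
    structure(list(significant_positive = logical(6),
                   significant_negative = logical(6),
                   atlas = atlas(c("A", "A", "C", "C"))),
              class = "cpm_consensus"))
  expect_error(difference_map(fa, other), "different atlases")
})

test_that("intra-network sums hit the analytic bounds and halved SV rule", {
  at <- atlas(rep(c("DMN", "X"), each = 3))
  N <- 6; E <- 15
  e12 <- edge_index(1, 2, N)
  # edge (1,2) selected positive in every fold of every iteration
  always <- sel_it(5, pos = rep(list(e12), 5))
  fm <- rep(list(always), 1000)
  hm <- intranetwork_heatmap(fake_fit(fm, E, 5, atlas = at), "DMN")
  expect_equal(hm$bound, 5000)
  expect_equal(hm$matrix["1", "2"], 5000)
  expect_equal(max(abs(hm$matrix)), 5000)
  # never selected -> 0
  expect_equal(hm$matrix["1", "3"], 0)
  # SV: row sum over the symmetric within-network matrix, halved
  expect_equal(hm$sv[["1"]], 5000 / 2)
  expect_equal(hm$sv[["3"]], 0)
  hm2 <- intranetwork_heatmap(fake_fit(fm, E, 5, atlas = at), "DMN",
                              halve = FALSE)
  expect_equal(hm2$sv[["1"]], 5000)
  # mixed signs: signed sum and hand-computed SV
  mix <- sel_it(3, pos = list(e12, e12, integer(0)),
                neg = list(integer(0), integer(0), edge_index(1, 3, N)))
  hm3 <- intranetwork_heatmap(fake_fit(rep(list(mix), 4), E, 3, atlas = at),
                              "DMN")
  expect_equal(hm3$matrix["1", "2"], 8)    # 2 folds x 4 iterations
  expect_equal(hm3$matrix["1", "3"], -4)
  expect_equal(hm3$sv[["1"]], (8 - 4) / 2)
  expect_true(all(abs(hm3$matrix) <= 3 * 4))
})
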