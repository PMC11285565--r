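#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Pick within- or between-network edges to plant signal on
#'
#' Deterministically samples `n_edges` distinct node pairs with both
#' endpoints in `network` (or one endpoint in each of two networks when
#' `network` has length 2), for use as a planted edge set in
#' [simulate_cohort].
#'
#' @param atlas A `cpm_atlas`.
#' @param network One network name (within-network edges) or two
#'   (between-network edges).
#' @param n_edges Number of edges to draw.
#' @param seed RNG seed for the draw.
#' @return Integer matrix with columns `i`, `j` (1-based, i < j).
#' @export
planted_edges <- function(atlas, network, n_edges, seed = 1L) {
  stopifnot(inherits(atlas, "cpm_atlas"), length(network) %in% 1:2)
  if (length(network) == 1L) {
    nodes <- network_nodes(atlas, network)
    if (length(nodes) < 2L) stop("network has fewer than 2 nodes")
    all_pairs <- t(utils::combn(nodes, 2L))
  } else {
    a <- network_nodes(atlas, network[1L])
    b <- network_nodes(atlas, network[2L])
    g <- expand.grid(i = a, j = b)
    g <- g[g$i != g$j, ]
    all_pairs <- cbind(pmin(g$i, g$j), pmax(g$i, g$j))
    all_pairs <- unique(all_pairs)
  }
  if (n_edges > nrow(all_pairs))
    stop("asked for ", n_edges, " edges but only ", nrow(all_pairs), " exist")
  sel <- with_seed(seed, sample.int(nrow(all_pairs), n_edges))
  out <- all_pairs[sel, , drop = FALSE]
  colnames(out) <- c("i", "j")
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

check_planted <- function(pairs, n, what) {
  if (is.null(pairs)) return(NULL)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1L] == pairs[, 2L])) stop(what, ": self-loops not allowed")
  if (any(pairs < 1L) || any(pairs > n)) stop(what, ": node index out of atlas range")
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (anyDuplicated(key)) stop(what, ": duplicate edges")
  cbind(i = pmin(pairs[, 1], pairs[, 2]), j = pmax(pairs[, 1], pairs[, 2]))
}

#' Simulate a cohort with known sex-specific predictive edges
#'
#' Generates a subject table and per-scan connectomes in which designated
#' edge sets carry linear signal for a latent memory propensity, separately
#' for female and male subjects, plus optional motion/age confound leakage
#' on designated edges. This gives every downstream stage (edge selection,
#' cross-validation, consensus, transfer, segregation) a known ground
#' truth.
#'
#' The generative model, per subject: a standardized latent memory
#' propensity `z ~ N(0, 1)` is drawn; each observed score is a monotone
#' discretization of `z` plus independent noise (`score_sd`) through a
#' logistic squash onto its legal integer range (FN-TR 0-10, RAVLT-L 0-75,
#' RAVLT-IR 0-15). Connectome edge weights are generated directly on the
#' Fisher-z scale as
#' `baseline + beta * z` (planted edges of the subject's sex only)
#' `+ motion_effect * ffd_std + age_effect * age_std` (confound edges)
#' `+ N(0, edge_sd)`, then symmetrised with zero diagonal. Each scan label
#' reuses the same latent `z` with independent edge noise and its own
#' motion value, emulating repeated scans of one subject.
#'
#' Under this model (and absent confound leakage on the edge) the
#' population correlation between a planted edge and the latent
#' propensity is `beta / sqrt(beta^2 + edge_sd^2)`; confound terms add
#' their variance to the denominator.
#'
#' @param atlas A `cpm_atlas` (default 268-node synthetic block atlas).
#' @param n_female,n_male Subjects per sex (default 200 each).
#' @param planted_female,planted_male Two-column matrices of node pairs
#'   (i, j), optionally with a third column of per-edge effect sizes; the
#'   edge sets carrying score signal in the respective sex. `NULL` plants
#'   nothing (null cohort).
#' @param beta Default effect size (standardized score units per unit
#'   Fisher-z) for planted edges lacking a third column.
#' @param confound_edges Node pairs receiving motion/age leakage; default
#'   is the union of both planted sets.
#' @param motion_effect,age_effect Confound effect sizes (Fisher-z units
#'   per SD of FFD / age) on confound edges.
#' @param baseline Baseline mean connectome: a scalar (every edge) or a
#'   symmetric N x N matrix on the Fisher-z scale.
#' @param edge_sd Between-subject edge noise SD (Fisher-z units).
#' @param score_sd SD of the score-specific noise added to `z` before
#'   discretization, in units of SD(z).
#' @param age_range Uniform age range in years.
#' @param ffd_mean,ffd_sd Mean/SD of the (truncated-normal, >= 0) per-scan
#'   maximum mean frame-to-frame displacement, mm.
#' @param scans Character vector of scan labels; one connectome set per
#'   label.
#' @param seed RNG seed; the whole cohort is bit-reproducible given the
#'   seed.
#' @return An object of class `cpm_cohort`: a list with elements
#'   `subjects` (data frame: id, sex, age, one `ffd_<scan>` column per
#'   scan, fn_tr, ravlt_l, ravlt_ir), `edges` (named list, one
#'   subjects x edges matrix per scan, canonical edge order), `atlas`,
#'   `truth` (planted edges, latent z, realized edge-score correlations
#'   per sex and scan) and `seed`.
#' @examples
#' a <- synthetic_atlas(30)
#' co <- simulate_cohort(a, n_female = 20, n_male = 20,
#'                       planted_female = planted_edges(a, "DMN", 3),
#'                       scans = "FACENAME", seed = 7)
#' head(co$subjects)
#' @export
simulate_cohort <- function(atlas = synthetic_atlas(),
                            n_female = 200L, n_male = 200L,
                            planted_female = NULL, planted_male = NULL,
                            beta = 0.5,
                            confound_edges = NULL,
                            motion_effect = 0.3, age_effect = 0.3,
                            baseline = 0.3,
                            edge_sd = 0.25, score_sd = 1,
                            age_range = c(36, 100),
                            ffd_mean = 0.14, ffd_sd = 0.06,
                            scans = "FACENAME",
                            seed = 1L) {
  stopifnot(inherits(atlas, "cpm_atlas"))
  n_female <- as.integer(n_female); n_male <- as.integer(n_male)
  if (n_female + n_male <= 0L) stop("subject count must be positive")
  if (edge_sd < 0 || score_sd < 0) stop("noise SDs must be non-negative")
  N <- n_nodes(atlas)
  E <- (N * (N - 1L)) %/% 2L

  pf <- check_planted(planted_female, N, "planted_female")
  pm <- check_planted(planted_male, N, "planted_male")
  beta_f <- if (!is.null(planted_female) && ncol(as.matrix(planted_female)) >= 3)
    as.numeric(as.matrix(planted_female)[, 3]) else rep(beta, NROW(pf))
  beta_m <- if (!is.null(planted_male) && ncol(as.matrix(planted_male)) >= 3)
    as.numeric(as.matrix(planted_male)[, 3]) else rep(beta, NROW(pm))
  if (!all(is.finite(c(beta_f, beta_m)))) stop("effect sizes must be finite")

  if (is.null(confound_edges)) {
    confound_edges <- rbind(pf, pm)
    if (!is.null(confound_edges))
      confound_edges <- unique(confound_edges)
  } else confound_edges <- check_planted(confound_edges, N, "confound_edges")

  ef <- if (NROW(pf)) edge_index(pf[, 1], pf[, 2], N) else integer(0)
  em <- if (NROW(pm)) edge_index(pm[, 1], pm[, 2], N) else integer(0)
  ec <- if (NROW(confound_edges))
    edge_index(confound_edges[, 1], confound_edges[, 2], N) else integer(0)

  if (is.matrix(baseline)) {
    baseline <- validate_connectome(baseline, atlas)
    base_vec <- vectorize_edges(baseline)
  } else base_vec <- rep(as.numeric(baseline), E)

  n <- n_female + n_male
  out <- with_seed(seed, {
    sex <- factor(rep(c("F", "M"), c(n_female, n_male)), levels = c("F", "M"))
    age <- stats::runif(n, age_range[1], age_range[2])
    z <- stats::rnorm(n)

    squash <- function(maxv) {
      zs <- z + score_sd * stats::rnorm(n)
      pmin(maxv, pmax(0, round(maxv * stats::plogis(zs))))
    }
    subjects <- data.frame(
      id = sprintf("S%04d", seq_len(n)), sex = sex, age = age,
      stringsAsFactors = FALSE)

    edges <- vector("list", length(scans)); names(edges) <- scans
    age_std <- as.numeric(scale(age))
    for (s in scans) {
      ffd <- abs(stats::rnorm(n, ffd_mean, ffd_sd))
      subjects[[paste0("ffd_", s)]] <- ffd
      ffd_std <- as.numeric(scale(ffd))
      X <- matrix(stats::rnorm(n * E, sd = edge_sd), n, E)
      X <- sweep(X, 2L, base_vec, `+`)
      if (length(ef))
        X[sex == "F", ef] <- X[sex == "F", ef] +
          outer(z[sex == "F"], beta_f)
      if (length(em))
        X[sex == "M", em] <- X[sex == "M", em] +
          outer(z[sex == "M"], beta_m)
      if (length(ec) && (motion_effect != 0 || age_effect != 0))
        X[, ec] <- X[, ec] + motion_effect * ffd_std + age_effect * age_std
      edges[[s]] <- X
    }
    subjects$fn_tr <- squash(10L)
    subjects$ravlt_l <- squash(75L)
    subjects$ravlt_ir <- squash(15L)
    list(subjects = subjects, edges = edges, z = z)
  })

  realized <- lapply(out$edges, function(X) {
    per_sex <- function(idx, edges_idx, pairs) {
      if (!length(edges_idx)) return(NULL)
      sc <- out$subjects[idx, c("fn_tr", "ravlt_l", "ravlt_ir")]
      data.frame(i = pairs[, 1], j = pairs[, 2], edge = edges_idx,
                 cor_z = as.numeric(stats::cor(X[idx, edges_idx, drop = FALSE],
                                               out$z[idx])),
                 cor_fn_tr = as.numeric(stats::cor(X[idx, edges_idx, drop = FALSE],
                                                   sc$fn_tr)),
                 cor_ravlt_l = as.numeric(stats::cor(X[idx, edges_idx, drop = FALSE],
                                                     sc$ravlt_l)),
                 cor_ravlt_ir = as.numeric(stats::cor(X[idx, edges_idx, drop = FALSE],
                                                      sc$ravlt_ir)))
    }
    list(female = per_sex(which(out$subjects$sex == "F"), ef, pf),
         male = per_sex(which(out$subjects$sex == "M"), em, pm))
  })

  structure(list(
    subjects = out$subjects,
    edges = out$edges,
    atlas = atlas,
    truth = list(planted_female = pf, planted_male = pm,
                 beta_female = beta_f, beta_male = beta_m,
                 confound_edges = confound_edges,
                 edge_female = ef, edge_male = em,
                 z = out$z, realized = realized,
                 edge_sd = edge_sd, score_sd = score_sd),
    seed = as.integer(seed)), class = "cpm_cohort")
}

#' @export
print.cpm_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$sex == "F"), "F /", sum(x$subjects$sex == "M"), "M ),",
      n_nodes(x$atlas), "nodes,", length(x$edges), "scan(s):",
      paste(names(x$edges), collapse = ", "), "\n")
  cat("Planted edges: F =", NROW(x$truth$planted_female),
      ", M =", NROW(x$truth$planted_male), "\n")
  invisible(x)
}

#' Simulate node time series with a target connectivity structure
#'
#' Draws multivariate normal frames whose population correlation matrix is
#' the inverse-Fisher transform of a connectome (unit diagonal). If that
#' target is not positive semidefinite it is first projected to the
#' nearest PSD correlation matrix ([Matrix::nearPD]); the Frobenius
#' projection distance is reported in the `proj_dist` attribute. The
#' empirical correlation of the output converges to the (projected)
#' target as `frames` grows.
#'
#' @param connectome Symmetric Fisher-z matrix (zero diagonal).
#' @param frames Number of time points; fewer than `nodes + 1` triggers a
#'   rank-deficiency warning.
#' @param seed RNG seed.
#' @return Nodes x frames numeric matrix with attribute `proj_dist`.
#' @export
simulate_timeseries <- function(connectome, frames, seed = 1L) {
  m <- validate_connectome(connectome)
  n <- nrow(m)
  frames <- as.integer(frames)
  if (frames < 1L) stop("frames must be positive")
  if (frames < n + 1L)
    warning("frames < nodes + 1: empirical correlation will be rank-deficient")
  r <- tanh(m)
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  proj_dist <- 0
  if (min(ev) < -1e-10) {
    pd <- Matrix::nearPD(r, corr = TRUE)
    r2 <- as.matrix(pd$mat)
    proj_dist <- sqrt(sum((r2 - r)^2))
    r <- r2
  }
  e <- eigen(r, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  out <- with_seed(seed, rt %*% matrix(stats::rnorm(n * frames), n, frames))
  attr(out, "proj_dist") <- proj_dist
  out
}

#' Exclude subjects by in-scanner head motion
#'
#' Removes any subject whose maximum mean frame-to-frame displacement
#' (FFD) exceeds `threshold` on any scan — strictly above, so a value
#' exactly at the threshold is kept. Subjects with a missing FFD value on
#' any scan are excluded with reason `"missing-motion"`.
#'
#' @param subjects Data frame with one or more `ffd_*` columns.
#' @param threshold Exclusion threshold in mm (default 0.3).
#' @return List with `subjects` (the retained rows) and `exclusions`
#'   (data frame: id, scan, ffd, reason — one row per offending scan).
#' @examples
#' d <- data.frame(id = c("a", "b", "c"), ffd_REST = c(0.1, 0.3, 0.31))
#' apply_motion_exclusion(d)$subjects$id
#' @export
apply_motion_exclusion <- function(subjects, threshold = 0.3) {
  stopifnot(is.data.frame(subjects), threshold > 0)
  ffd_cols <- grep("^ffd_", names(subjects), value = TRUE)
  if (nrow(subjects) == 0L)
    return(list(subjects = subjects,
                exclusions = data.frame(id = character(0), scan = character(0),
                                        ffd = numeric(0), reason = character(0))))
  if (!length(ffd_cols)) stop("no ffd_* columns found")
  logs <- list()
  drop <- logical(nrow(subjects))
  for (col in ffd_cols) {
    v <- subjects[[col]]
    scan <- sub("^ffd_", "", col)
    bad <- !is.na(v) & v > threshold
    mis <- is.na(v)
    if (any(bad))
      logs[[length(logs) + 1L]] <- data.frame(
        id = as.character(subjects$id[bad]), scan = scan, ffd = v[bad],
        reason = "above-threshold", stringsAsFactors = FALSE)
    if (any(mis))
      logs[[length(logs) + 1L]] <- data.frame(
        id = as.character(subjects$id[mis]), scan = scan, ffd = NA_real_,
        reason = "missing-motion", stringsAsFactors = FALSE)
    drop <- drop | bad | mis
  }
  exclusions <- if (length(logs)) do.call(rbind, logs) else
    data.frame(id = character(0), scan = character(0),
               ffd = numeric(0), reason = character(0))
  list(subjects = subjects[!drop, , drop = FALSE], exclusions = exclusions)
}

#' Filter a cohort's subjects and connectomes together
#'
#' @param cohort A `cpm_cohort`.
#' @param keep Logical or integer index over subjects.
#' @return The subsetted `cpm_cohort` (truth's latent z subsetted too).
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  cohort$subjects <- cohort$subjects[keep, , drop = FALSE]
  cohort$edges <- lapply(cohort$edges, function(X) X[keep, , drop = FALSE])
  cohort$truth$z <- cohort$truth$z[keep]
  cohort
}
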