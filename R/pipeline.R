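#' Deterministic seed derivation for pipeline stages
#'
#' Derives a stage seed from the global seed and a sequence of labels by
#' a fixed polynomial hash of the labels' bytes (modulo 2^31 - 1), so
#' any subset of the pipeline can be re-run reproducibly.
#'
#' @param seed Global integer seed.
#' @param ... Character/numeric labels (stage, group, scan, score, ...).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(lab)) h <- (h * 131 + b) %% 2147483647
  as.integer(h + 1)
}

#' Run the full CPM study pipeline on a cohort
#'
#' Orchestrates every stage over a grid of subject groups, scans and
#' scores: model fitting ([cpm]), permutation significance
#' ([cpm_permute]) with Benjamini-Hochberg correction per group across
#' the scan x score family, female-vs-male performance comparison,
#' consensus-edge and network analyses for a designated model
#' ([consensus_edges], [summarize_internetwork], [difference_map],
#' [intranetwork_heatmap]), cross-sex model transfer ([cpm_transfer]),
#' and the association-ratio segregation table ([compare_segregation]).
#' Re-running with an identical cohort, configuration and seed
#' reproduces identical machine-readable outputs.
#'
#' @param cohort A `cpm_cohort`, or a directory written by
#'   [write_cohort].
#' @param scores Score columns to model (default the three memory
#'   scores).
#' @param scans Scan labels (default all in the cohort).
#' @param groups Subject groups: any of `"all"`, `"F"`, `"M"`.
#' @param k,n_iterations,alpha,mode Passed to [cpm]. Defaults depend on
#'   `profile`: `"paper"` uses 5 folds, 1000 iterations and 1000
#'   permutations; `"test"` uses 5 folds, 50 iterations, 50
#'   permutations.
#' @param n_perm Permutations per model (see `profile`).
#' @param consensus_scan,consensus_score The model whose consensus,
#'   network and transfer analyses are produced (defaults: the FACENAME
#'   scan if present else the first scan; the ravlt_ir score if modelled
#'   else the first score).
#' @param intranet_network Network for the intra-network heatmap
#'   (default DMN).
#' @param seg_networks Networks entering the segregation comparison.
#' @param profile `"test"` or `"paper"`: fixes the default counts above.
#' @param seed Global seed; stage seeds are derived from it (see
#'   [derive_seed]).
#' @param out_dir Optional directory for machine-readable outputs
#'   (CSV/TSV/JSON).
#' @param apply_exclusion Apply the 0.3 mm motion exclusion before
#'   modelling (default TRUE).
#' @return Object of class `cpm_study`: `performance` (one row per
#'   group x scan x score with rho, RMSE, raw and BH-adjusted permutation
#'   p), `sex_comparison`, `consensus` (per-sex consensus objects and
#'   inter-network summaries), `difference`, `intranet`, `transfer`,
#'   `segregation`, `exclusions`, `config`.
#' @export
run_cpm_study <- function(cohort,
                          scores = c("fn_tr", "ravlt_l", "ravlt_ir"),
                          scans = NULL,
                          groups = c("all", "F", "M"),
                          k = 5L, n_iterations = NULL, alpha = 0.01,
                          mode = "combined", n_perm = NULL,
                          consensus_scan = NULL, consensus_score = NULL,
                          intranet_network = "DMN",
                          seg_networks = c("DMN", "VI", "VII", "VAs"),
                          profile = c("test", "paper"),
                          seed = 1L, out_dir = NULL,
                          apply_exclusion = TRUE) {
  profile <- match.arg(profile)
  if (is.character(cohort) && length(cohort) == 1L)
    cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cpm_cohort"))
  if (is.null(n_iterations))
    n_iterations <- if (profile == "paper") 1000L else 50L
  if (is.null(n_perm)) n_perm <- if (profile == "paper") 1000L else 50L
  if (is.null(scans)) scans <- names(cohort$edges)
  scores <- intersect(scores, names(cohort$subjects))
  if (!length(scores)) stop("no requested score columns in the cohort")
  if (is.null(consensus_scan))
    consensus_scan <- if ("FACENAME" %in% scans) "FACENAME" else scans[1L]
  if (is.null(consensus_score))
    consensus_score <- if ("ravlt_ir" %in% scores) "ravlt_ir" else scores[1L]

  exclusions <- NULL
  if (apply_exclusion) {
    mx <- apply_motion_exclusion(cohort$subjects)
    exclusions <- mx$exclusions
    if (nrow(exclusions))
      cohort <- subset_cohort(cohort,
                              cohort$subjects$id %in% mx$subjects$id)
  }

  group_idx <- function(g) switch(g,
    all = rep(TRUE, nrow(cohort$subjects)),
    F = cohort$subjects$sex == "F",
    M = cohort$subjects$sex == "M",
    stop("unknown group: ", g))

  perf <- list()
  fits <- list()
  for (g in groups) for (s in scans) for (sc in scores) {
    sub <- subset_cohort(cohort, group_idx(g))
    fml <- stats::as.formula(paste0(sc, " ~ ffd_", s, " * age"))
    fit <- cpm(fml, sub, scan = s, k = k, n_iterations = n_iterations,
               alpha = alpha, mode = mode,
               seed = derive_seed(seed, "cpm", g, s, sc))
    pm <- cpm_permute(fit, n_perm = n_perm,
                      seed = derive_seed(seed, "perm", g, s, sc))
    perf[[length(perf) + 1L]] <- data.frame(
      group = g, scan = s, score = sc, n = fit$n,
      rho_median = fit$rho[fit$median], rmse_median = fit$rmse[fit$median],
      p_raw = pm$p, stringsAsFactors = FALSE)
    fits[[paste(g, s, sc, sep = ".")]] <- fit
  }
  perf <- do.call(rbind, perf)
  perf$p_bh <- NA_real_
  for (g in groups) {
    idx <- perf$group == g
    perf$p_bh[idx] <- bh_adjust(perf$p_raw[idx])
  }

  sex_cmp <- NULL
  if (all(c("F", "M") %in% groups)) {
    rows <- list()
    for (s in scans) for (sc in scores) {
      ff <- fits[[paste("F", s, sc, sep = ".")]]
      fm <- fits[[paste("M", s, sc, sep = ".")]]
      w <- compare_group_performance(ff$rho, fm$rho)
      rows[[length(rows) + 1L]] <- data.frame(
        scan = s, score = sc, W = w$statistic, p = w$p,
        stringsAsFactors = FALSE)
    }
    sex_cmp <- do.call(rbind, rows)
  }

  consensus <- difference <- intranet <- transfer <- NULL
  if (all(c("F", "M") %in% groups)) {
    ff <- fits[[paste("F", consensus_scan, consensus_score, sep = ".")]]
    fm <- fits[[paste("M", consensus_scan, consensus_score, sep = ".")]]
    cf <- consensus_edges(ff); cm <- consensus_edges(fm)
    sf <- summarize_internetwork(cf); sm <- summarize_internetwork(cm)
    consensus <- list(F = list(consensus = cf, internetwork = sf),
                      M = list(consensus = cm, internetwork = sm))
    difference <- difference_map(sf, sm)
    intranet <- list(F = intranetwork_heatmap(ff, intranet_network),
                     M = intranetwork_heatmap(fm, intranet_network))
    transfer <- list(
      F_to_M = cpm_transfer(ff, cohort, scan = consensus_scan,
                            subset = sex == "M"),
      M_to_F = cpm_transfer(fm, cohort, scan = consensus_scan,
                            subset = sex == "F"))
  }

  segregation <- compare_segregation(cohort, networks = seg_networks,
                                     scans = scans)

  config <- list(scores = scores, scans = scans, groups = groups, k = k,
                 n_iterations = n_iterations, alpha = alpha, mode = mode,
                 n_perm = n_perm, consensus_scan = consensus_scan,
                 consensus_score = consensus_score,
                 intranet_network = intranet_network,
                 seg_networks = seg_networks, profile = profile,
                 seed = seed)
  study <- structure(list(performance = perf, sex_comparison = sex_cmp,
                          consensus = consensus, difference = difference,
                          intranet = intranet, transfer = transfer,
                          segregation = segregation,
                          exclusions = exclusions, config = config),
                     class = "cpm_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Write a study's machine-readable outputs
#'
#' @param study A `cpm_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  if (!is.null(study$sex_comparison))
    utils::write.csv(study$sex_comparison,
                     file.path(dir, "sex_comparison.csv"), row.names = FALSE)
  if (!is.null(study$consensus)) {
    for (g in names(study$consensus)) {
      write_consensus(study$consensus[[g]]$consensus,
                      file.path(dir, paste0("consensus_", g, ".tsv")))
      for (sgn in c("positive", "negative"))
        utils::write.csv(study$consensus[[g]]$internetwork[[sgn]],
                         file.path(dir, paste0("internetwork_", g, "_",
                                               sgn, ".csv")))
    }
    for (sgn in c("positive", "negative"))
      utils::write.csv(study$difference[[sgn]],
                       file.path(dir, paste0("internetwork_diff_",
                                             sgn, ".csv")))
  }
  utils::write.csv(as.data.frame(study$segregation),
                   file.path(dir, "segregation.csv"), row.names = FALSE)
  if (!is.null(study$exclusions))
    utils::write.csv(study$exclusions, file.path(dir, "exclusions.csv"),
                     row.names = FALSE)
  jsonlite::write_json(study$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.cpm_study <- function(x, ...) {
  cat("CPM study:", nrow(x$performance), "models (",
      paste(x$config$groups, collapse = "/"), "x",
      length(x$config$scans), "scan(s) x", length(x$config$scores),
      "score(s) ),", x$config$n_iterations, "iterations,",
      x$config$n_perm, "permutations\n\n")
  report(x)
}

#' Human-readable study report
#'
#' Prints the performance grid (rho, RMSE, raw and BH-adjusted
#' permutation p per group/scan/score), the sex performance comparison,
#' consensus-edge counts and inter-network difference maps, the
#' intra-network summed vectors, transfer performance, and the
#' segregation table. Stages absent from the study are noted and
#' skipped.
#'
#' @param study A `cpm_study`.
#' @return The study, invisibly.
#' @export
report <- function(study) {
  stopifnot(inherits(study, "cpm_study"))
  perf <- study$performance
  perf$p_display <- vapply(perf$p_raw, format_perm_p,
                           n_perm = study$config$n_perm, character(1))
  cat("== Model performance (median iteration) ==\n")
  print(perf[, c("group", "scan", "score", "n", "rho_median",
                 "rmse_median", "p_display", "p_bh")],
        row.names = FALSE, digits = 4)
  if (!is.null(study$sex_comparison)) {
    cat("\n== Female vs male iteration performance (rank-sum) ==\n")
    print(study$sex_comparison, row.names = FALSE, digits = 4)
  }
  if (!is.null(study$consensus)) {
    cat("\n== Consensus edges (", study$config$consensus_score, ", scan ",
        study$config$consensus_scan, ") ==\n", sep = "")
    for (g in names(study$consensus)) {
      cns <- study$consensus[[g]]$consensus
      np <- sum(cns$significant_positive); nn <- sum(cns$significant_negative)
      if (np + nn == 0)
        cat("  ", g, ": no significant edges\n")
      else cat("  ", g, ":", np, "positive,", nn, "negative\n")
    }
    cat("\n== Inter-network difference map (F - M) ==\n")
    print(study$difference)
  } else cat("\n(consensus stage not run: needs both F and M groups)\n")
  if (!is.null(study$intranet)) {
    cat("\n== Intra-", study$config$intranet_network,
        " summed vectors (top nodes) ==\n", sep = "")
    for (g in names(study$intranet)) {
      sv <- study$intranet[[g]]$sv
      cat("  ", g, ": ")
      top <- utils::head(sort(abs(sv), decreasing = TRUE), 3)
      cat(paste(names(top), round(sv[names(top)], 1), collapse = ", "), "\n")
    }
  }
  if (!is.null(study$transfer)) {
    cat("\n== Cross-sex transfer ==\n")
    for (g in names(study$transfer)) {
      tr <- study$transfer[[g]]
      cat("  ", g, ": median rho =", round(tr$rho[tr$median], 4), "\n")
    }
  }
  cat("\n== Network segregation (F vs M) ==\n")
  print(study$segregation)
  invisible(study)
}
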