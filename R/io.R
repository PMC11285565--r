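#' Write / read a cohort as plain-text files
#'
#' Serialises a cohort to the package's interchange layout under `dir`:
#' `subjects.csv` (id, sex, age, ffd_* per scan, the three scores),
#' `atlas.tsv`, one whitespace-delimited N x N matrix per subject per
#' scan under `connectomes/`, a `manifest.csv` (subject_id, scan_label,
#' path) and, when ground truth is present, `truth.json`.
#' `read_cohort` reconstructs the `cpm_cohort` (edge matrices re-derived
#' from the matrix files; ground truth restored from the JSON when
#' available).
#'
#' @param cohort A `cpm_cohort`.
#' @param dir Directory to create/populate.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `cpm_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  dir.create(file.path(dir, "connectomes"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  N <- n_nodes(cohort$atlas)
  manifest <- list()
  for (s in names(cohort$edges)) {
    X <- cohort$edges[[s]]
    for (r in seq_len(nrow(X))) {
      id <- cohort$subjects$id[r]
      rel <- file.path("connectomes", paste0(id, "_", s, ".txt"))
      write_connectome(devectorize_edges(X[r, ], N), file.path(dir, rel))
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = id, scan_label = s, path = rel,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, manifest), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  tr <- cohort$truth
  if (!is.null(tr)) {
    jsonlite::write_json(list(
      planted_female = tr$planted_female, planted_male = tr$planted_male,
      beta_female = tr$beta_female, beta_male = tr$beta_male,
      z = tr$z, edge_sd = tr$edge_sd, score_sd = tr$score_sd,
      seed = cohort$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  subjects$sex <- factor(subjects$sex, levels = c("F", "M"))
  atl <- read_atlas(file.path(dir, "atlas.tsv"))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  N <- n_nodes(atl)
  E <- (N * (N - 1L)) %/% 2L
  edges <- list()
  for (s in unique(manifest$scan_label)) {
    ms <- manifest[manifest$scan_label == s, ]
    X <- matrix(NA_real_, nrow(subjects), E)
    ord <- match(ms$subject_id, subjects$id)
    if (anyNA(ord)) stop("manifest references unknown subject ids")
    for (r in seq_len(nrow(ms)))
      X[ord[r], ] <- vectorize_edges(
        read_connectome(file.path(dir, ms$path[r]), atl))
    if (anyNA(X)) stop("manifest does not cover every subject for scan ", s)
    edges[[s]] <- X
  }
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) {
    tj <- jsonlite::read_json(tp, simplifyVector = TRUE)
    truth <- list(planted_female = if (!is.null(tj$planted_female))
                    as.matrix(tj$planted_female),
                  planted_male = if (!is.null(tj$planted_male))
                    as.matrix(tj$planted_male),
                  beta_female = tj$beta_female, beta_male = tj$beta_male,
                  z = tj$z, edge_sd = tj$edge_sd, score_sd = tj$score_sd)
  }
  structure(list(subjects = subjects, edges = edges, atlas = atl,
                 truth = truth,
                 seed = NA_integer_), class = "cpm_cohort")
}
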