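#' Association ratio: weighted network segregation
#'
#' For one network of an atlas, the ratio of the weighted sum of its
#' within-network edges to the weighted sum of all edges incident to the
#' network's nodes (each unordered edge counted once):
#'
#' `ratio = sum(within) / (sum(within) + sum(boundary))`
#'
#' where boundary edges have exactly one endpoint in the network. Higher
#' values mean the network's connectivity is concentrated within itself,
#' i.e. higher segregation. Weights are used raw and signed (Fisher-z
#' scale, no thresholding); for non-negative weights the ratio lies in
#' [0, 1], is invariant to global rescaling, and moves monotonically with
#' added within- vs between-network weight. The strict boundary-only
#' denominator (a within/boundary odds) is available via
#' `denominator = "boundary"`. A denominator smaller in magnitude than
#' `tol` makes the ratio undefined (`NA`, with a warning).
#'
#' @param connectome Symmetric weighted matrix, or an edge vector in
#'   canonical order.
#' @param atlas A `cpm_atlas`.
#' @param network Network name (must have >= 2 nodes).
#' @param denominator `"all"` (within + boundary, default) or
#'   `"boundary"`.
#' @param tol Near-zero denominator guard (default 1e-12).
#' @return Numeric scalar.
#' @examples
#' a <- atlas(c("A", "A", "B", "B"))
#' w <- devectorize_edges(rep(1, 6))
#' association_ratio(w, a, "A")  # 1 / (1 + 4) = 0.2
#' @export
association_ratio <- function(connectome, atlas, network,
                              denominator = c("all", "boundary"),
                              tol = 1e-12) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(atlas, "cpm_atlas"))
  N <- n_nodes(atlas)
  v <- if (is.matrix(connectome)) vectorize_edges(validate_connectome(
    connectome, atlas)) else {
    if (length(connectome) != N * (N - 1L) / 2L)
      stop("edge vector length does not match atlas")
    as.numeric(connectome)
  }
  nodes <- network_nodes(atlas, network)
  if (length(nodes) < 2L) stop("network ", network, " has fewer than 2 nodes")
  ep <- edge_pairs(N)
  in_i <- ep[, 1L] %in% nodes
  in_j <- ep[, 2L] %in% nodes
  within <- sum(v[in_i & in_j])
  boundary <- sum(v[xor(in_i, in_j)])
  den <- if (denominator == "all") within + boundary else boundary
  if (abs(den) < tol) {
    warning("association ratio undefined: near-zero denominator for ",
            network)
    return(NA_real_)
  }
  within / den
}

#' Per-subject association ratios across a cohort
#'
#' Computes [association_ratio] for every subject, scan and requested
#' network of a cohort in one pass (vectorised over the edge matrices).
#'
#' @param cohort A `cpm_cohort`.
#' @param networks Network names (default the DMN and the three visual
#'   networks).
#' @param scans Scan labels (default all in the cohort).
#' @inheritParams association_ratio
#' @return Long data frame: id, sex, scan, network, ratio.
#' @export
association_ratio_table <- function(cohort,
                                    networks = c("DMN", "VI", "VII", "VAs"),
                                    scans = names(cohort$edges),
                                    denominator = c("all", "boundary"),
                                    tol = 1e-12) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(cohort, "cpm_cohort"))
  N <- n_nodes(cohort$atlas)
  ep <- edge_pairs(N)
  out <- list()
  for (net in networks) {
    nodes <- network_nodes(cohort$atlas, net)
    if (length(nodes) < 2L) stop("network ", net, " has fewer than 2 nodes")
    in_i <- ep[, 1L] %in% nodes
    in_j <- ep[, 2L] %in% nodes
    w_within <- as.numeric(in_i & in_j)
    w_bound <- as.numeric(xor(in_i, in_j))
    for (s in scans) {
      X <- cohort$edges[[s]]
      num <- as.numeric(X %*% w_within)
      den <- if (denominator == "all") num + as.numeric(X %*% w_bound)
             else as.numeric(X %*% w_bound)
      ratio <- ifelse(abs(den) < tol, NA_real_, num / den)
      out[[length(out) + 1L]] <- data.frame(
        id = cohort$subjects$id, sex = cohort$subjects$sex,
        scan = s, network = net, ratio = ratio, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare network segregation between two groups
#'
#' For each (network, scan) cell, a two-sample t-test (pooled variance by
#' default) of the association ratio between female and male subjects;
#' positive t means higher segregation in females. Benjamini-Hochberg
#' correction is applied within each network across the scans tested
#' (`family = "per-network"`, the default) or across all cells
#' (`family = "all"`).
#'
#' @param cohort A `cpm_cohort` (or a long table from
#'   [association_ratio_table] via the `ratios` argument).
#' @param networks,scans Networks and scans to test.
#' @param ratios Optional precomputed long table (overrides `cohort`).
#' @param var_equal Pooled-variance (Student) t when TRUE (default);
#'   Welch otherwise.
#' @param family BH family: `"per-network"` or `"all"`.
#' @param q Rejection level for the BH-survival flag (default 0.05).
#' @inheritParams association_ratio
#' @return Object of class `cpm_segregation`: data frame with columns
#'   scan, network, n_f, n_m, mean_f, mean_m, t, p, p_bh, survives.
#'   Cells with fewer than 2 subjects per group are skipped with a log
#'   entry in `attr(, "skipped")`.
#' @export
compare_segregation <- function(cohort,
                                networks = c("DMN", "VI", "VII", "VAs"),
                                scans = NULL, ratios = NULL,
                                var_equal = TRUE,
                                family = c("per-network", "all"),
                                q = 0.05,
                                denominator = c("all", "boundary")) {
  family <- match.arg(family)
  denominator <- match.arg(denominator)
  if (is.null(ratios)) {
    if (is.null(scans)) scans <- names(cohort$edges)
    ratios <- association_ratio_table(cohort, networks, scans,
                                      denominator = denominator)
  } else if (is.null(scans)) scans <- unique(ratios$scan)
  rows <- list(); skipped <- list()
  for (net in networks) for (s in scans) {
    cell <- ratios[ratios$network == net & ratios$scan == s &
                     !is.na(ratios$ratio), ]
    f <- cell$ratio[cell$sex == "F"]
    m <- cell$ratio[cell$sex == "M"]
    if (length(f) < 2L || length(m) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        scan = s, network = net, n_f = length(f), n_m = length(m))
      next
    }
    ht <- stats::t.test(f, m, var.equal = var_equal)
    rows[[length(rows) + 1L]] <- data.frame(
      scan = s, network = net, n_f = length(f), n_m = length(m),
      mean_f = mean(f), mean_m = mean(m),
      t = unname(ht$statistic), p = ht$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable (network, scan) cells")
  tab <- do.call(rbind, rows)
  if (family == "per-network") {
    tab$p_bh <- NA_real_
    for (net in unique(tab$network)) {
      idx <- tab$network == net
      tab$p_bh[idx] <- bh_adjust(tab$p[idx])
    }
  } else tab$p_bh <- bh_adjust(tab$p)
  tab$survives <- tab$p_bh < q
  structure(tab, class = c("cpm_segregation", "data.frame"),
            skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
            var_equal = var_equal, family = family, q = q)
}

#' @export
print.cpm_segregation <- function(x, ...) {
  cat("Network segregation, female vs male (positive t: female higher)\n")
  wide <- stats::reshape(
    data.frame(scan = x$scan, network = x$network,
               cell = sprintf("%.2f (%.3g)%s", x$t, x$p,
                              ifelse(x$survives, "", "†"))),
    idvar = "scan", timevar = "network", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  cat("† did not survive BH correction (",
      attr(x, "family"), " family, q = ", attr(x, "q"), ")\n", sep = "")
  invisible(x)
}
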