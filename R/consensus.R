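#' Consensus ("significant") edges across folds and iterations
#'
#' From a fitted CPM's stored per-fold edge selections, counts for every
#' edge and sign (i) the total number of fold-level selections over all
#' `k x n_iterations` folds, and (ii) the number of iterations in which
#' the edge was selected in at least `min_folds` of the k folds
#' ("qualifying" iterations). An edge is significant for a sign when its
#' qualifying count reaches `iteration_frac * n_iterations` (the
#' comparison is `>=`). With the defaults (k = 5, `min_folds = 2`,
#' `iteration_frac = 0.4`, 1000 iterations) this is the
#' 2-of-5-folds-in-40%-of-iterations rule. For non-default k,
#' `min_folds` defaults to `ceiling(0.4 * k)`.
#'
#' If an edge meets the criterion in both signs, it is assigned the sign
#' with the larger qualifying count; an exact tie excludes the edge (the
#' dropped edges are recorded in `tied_edges`).
#'
#' @param object A fitted `cpm`.
#' @param min_folds Minimum folds per iteration (default
#'   `ceiling(0.4 * k)`, i.e. 2 of 5).
#' @param iteration_frac Required fraction of qualifying iterations
#'   (default 0.4).
#' @return Object of class `cpm_consensus`: per-sign integer vectors
#'   `fold_count_*` (0..k*n_iterations) and `qualifying_*`
#'   (0..n_iterations), logical `significant_*` per edge, the thresholds,
#'   the atlas, and `tied_edges`.
#' @export
consensus_edges <- function(object, min_folds = NULL, iteration_frac = 0.4) {
  stopifnot(inherits(object, "cpm"))
  if (is.null(object$fold_models))
    stop("fitted object carries no stored selections")
  k <- object$k
  if (is.null(min_folds)) min_folds <- ceiling(0.4 * k)
  if (!(iteration_frac > 0 && iteration_frac <= 1))
    stop("iteration_frac must be in (0, 1]")
  E <- ncol(object$x)
  fold_pos <- integer(E); fold_neg <- integer(E)
  qual_pos <- integer(E); qual_neg <- integer(E)
  for (it in object$fold_models) {
    cp <- tabulate(unlist(lapply(it, `[[`, "positive"), use.names = FALSE), E)
    cn <- tabulate(unlist(lapply(it, `[[`, "negative"), use.names = FALSE), E)
    fold_pos <- fold_pos + cp
    fold_neg <- fold_neg + cn
    qual_pos <- qual_pos + (cp >= min_folds)
    qual_neg <- qual_neg + (cn >= min_folds)
  }
  need <- iteration_frac * object$n_iterations
  sig_pos <- qual_pos >= need
  sig_neg <- qual_neg >= need
  both <- which(sig_pos & sig_neg)
  tied <- integer(0)
  if (length(both)) {
    keep_pos <- qual_pos[both] > qual_neg[both]
    keep_neg <- qual_neg[both] > qual_pos[both]
    tied <- both[!keep_pos & !keep_neg]
    sig_pos[both[!keep_pos]] <- FALSE
    sig_neg[both[!keep_neg]] <- FALSE
  }
  structure(list(fold_count_positive = fold_pos,
                 fold_count_negative = fold_neg,
                 qualifying_positive = qual_pos,
                 qualifying_negative = qual_neg,
                 significant_positive = sig_pos,
                 significant_negative = sig_neg,
                 tied_edges = tied,
                 k = k, n_iterations = object$n_iterations,
                 min_folds = min_folds, iteration_frac = iteration_frac,
                 atlas = object$atlas), class = "cpm_consensus")
}

#' @export
print.cpm_consensus <- function(x, ...) {
  cat(sprintf("Consensus edges (>= %d of %d folds in >= %g%% of %d iterations)\n",
              x$min_folds, x$k, 100 * x$iteration_frac, x$n_iterations))
  cat("  significant positive:", sum(x$significant_positive),
      " negative:", sum(x$significant_negative),
      if (length(x$tied_edges)) paste0(" (", length(x$tied_edges),
                                       " tied, excluded)"), "\n")
  invisible(x)
}

#' Write a consensus edge table as TSV
#'
#' One row per edge ever selected, with 0-based node indices, per-sign
#' fold counts, qualifying-iteration counts and significance flags.
#'
#' @param consensus A `cpm_consensus`.
#' @param path Output file.
#' @export
write_consensus <- function(consensus, path) {
  n <- n_nodes(consensus$atlas)
  ep <- edge_pairs(n)
  keep <- consensus$fold_count_positive > 0 | consensus$fold_count_negative > 0
  d <- data.frame(node_i = ep[keep, 1L] - 1L, node_j = ep[keep, 2L] - 1L,
                  fold_count_pos = consensus$fold_count_positive[keep],
                  fold_count_neg = consensus$fold_count_negative[keep],
                  qualifying_pos = consensus$qualifying_positive[keep],
                  qualifying_neg = consensus$qualifying_negative[keep],
                  significant_pos = consensus$significant_positive[keep],
                  significant_neg = consensus$significant_negative[keep])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Inter-network summary of significant edges
#'
#' Counts the significant edges between each pair of networks and
#' normalizes by the total number of possible edges between the pair:
#' `|A| * |B|` for distinct networks, `|A| * (|A| - 1) / 2` within a
#' network. Produced separately for the positive and negative consensus
#' matrices. A network with fewer than 2 nodes has an undefined
#' within-network cell (`NA`).
#'
#' @param consensus A `cpm_consensus` (its atlas is used unless `atlas`
#'   is given).
#' @param atlas Optional `cpm_atlas` override.
#' @return Object of class `cpm_network_summary`: list with symmetric
#'   matrices `positive` and `negative` (networks x networks, values in
#'   [0, 1]), plus raw `count_positive` / `count_negative` matrices.
#' @export
summarize_internetwork <- function(consensus, atlas = NULL) {
  stopifnot(inherits(consensus, "cpm_consensus"))
  atlas <- atlas %||% consensus$atlas
  if (is.null(atlas)) stop("no atlas available")
  N <- n_nodes(atlas)
  nets <- levels(atlas$network)
  lab <- as.integer(atlas$network)
  sizes <- tabulate(lab, nbins = length(nets))
  ep <- edge_pairs(N)
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1) / 2
  dimnames(denom) <- list(nets, nets)

  one_sign <- function(sig) {
    cnt <- matrix(0L, length(nets), length(nets), dimnames = list(nets, nets))
    if (any(sig)) {
      a <- lab[ep[sig, 1L]]; b <- lab[ep[sig, 2L]]
      for (idx in seq_along(a)) {
        cnt[a[idx], b[idx]] <- cnt[a[idx], b[idx]] + 1L
        if (a[idx] != b[idx]) cnt[b[idx], a[idx]] <- cnt[b[idx], a[idx]] + 1L
      }
    }
    norm <- cnt / denom
    norm[denom == 0] <- NA_real_
    list(count = cnt, norm = norm)
  }
  pos <- one_sign(consensus$significant_positive)
  neg <- one_sign(consensus$significant_negative)
  structure(list(positive = pos$norm, negative = neg$norm,
                 count_positive = pos$count, count_negative = neg$count,
                 n_possible = denom, networks = nets),
            class = "cpm_network_summary")
}

#' @export
print.cpm_network_summary <- function(x, digits = 3, ...) {
  cat("Inter-network significant-edge density (positive):\n")
  print(round(x$positive, digits))
  cat("Inter-network significant-edge density (negative):\n")
  print(round(x$negative, digits))
  invisible(x)
}

#' Cellwise difference between two inter-network summaries
#'
#' Subtracts one group's normalized inter-network table from another's
#' (e.g. female minus male), per sign.
#'
#' @param summary_a,summary_b Two `cpm_network_summary` objects on the
#'   same atlas (a - b).
#' @return Object of class `cpm_network_diff` with `positive` and
#'   `negative` signed matrices.
#' @export
difference_map <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "cpm_network_summary"),
            inherits(summary_b, "cpm_network_summary"))
  if (!identical(summary_a$networks, summary_b$networks) ||
      !identical(dim(summary_a$positive), dim(summary_b$positive)))
    stop("summaries come from different atlases")
  structure(list(positive = summary_a$positive - summary_b$positive,
                 negative = summary_a$negative - summary_b$negative,
                 networks = summary_a$networks),
            class = "cpm_network_diff")
}

#' @export
print.cpm_network_diff <- function(x, digits = 3, ...) {
  cat("Inter-network difference map (positive):\n")
  print(round(x$positive, digits))
  cat("Inter-network difference map (negative):\n")
  print(round(x$negative, digits))
  invisible(x)
}

#' Intra-network signed edge-selection heatmap and summed vector
#'
#' For every edge with both endpoints in one network, the signed
#' selection sum over all folds and iterations:
#' (number of positive fold-selections) - (number of negative
#' fold-selections), bounded by +/- (k x n_iterations) — +/-5000 under
#' the canonical 5-fold, 1000-iteration settings. The node-level summed
#' vector (SV) is each node's row sum over the symmetric within-network
#' matrix divided by 2 (the halving compensates the symmetric double
#' storage; set `halve = FALSE` for the unhalved variant).
#'
#' @param object A fitted `cpm`.
#' @param network Network name.
#' @param atlas Optional atlas override.
#' @param halve Divide row sums by 2 (default TRUE).
#' @return Object of class `cpm_intranet`: `matrix` (nodes-in-network
#'   square, signed sums), `sv` (named numeric), `bound`
#'   (k x n_iterations), `nodes`.
#' @export
intranetwork_heatmap <- function(object, network, atlas = NULL,
                                 halve = TRUE) {
  stopifnot(inherits(object, "cpm"))
  atlas <- atlas %||% object$atlas
  if (is.null(atlas)) stop("no atlas available")
  nodes <- network_nodes(atlas, network)
  N <- n_nodes(atlas)
  E <- ncol(object$x)
  fold_pos <- integer(E); fold_neg <- integer(E)
  for (it in object$fold_models) {
    fold_pos <- fold_pos + tabulate(unlist(lapply(it, `[[`, "positive"),
                                           use.names = FALSE), E)
    fold_neg <- fold_neg + tabulate(unlist(lapply(it, `[[`, "negative"),
                                           use.names = FALSE), E)
  }
  signed <- devectorize_edges(fold_pos - fold_neg, N)
  m <- signed[nodes, nodes, drop = FALSE]
  dimnames(m) <- list(nodes, nodes)
  sv <- rowSums(m)
  if (halve) sv <- sv / 2
  structure(list(matrix = m, sv = sv, network = network, nodes = nodes,
                 bound = object$k * object$n_iterations, halved = halve),
            class = "cpm_intranet")
}

#' @export
print.cpm_intranet <- function(x, ...) {
  cat(sprintf("Intra-%s signed selection sums: %d nodes, bound +/- %d\n",
              x$network, length(x$nodes), x$bound))
  cat("  top nodes by |SV|:\n")
  print(utils::head(sort(abs(x$sv), decreasing = TRUE), 5))
  invisible(x)
}

#' @export
plot.cpm_intranet <- function(x, ...) {
  m <- x$matrix
  lim <- max(1, max(abs(m)))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  zlim = c(-lim, lim), col = pal,
                  xlab = "node", ylab = "node",
                  main = paste0("Intra-", x$network,
                                " signed edge-selection sums"), ...)
  invisible(x)
}

#' @export
plot.cpm_network_summary <- function(x, sign = c("positive", "negative"),
                                     ...) {
  sign <- match.arg(sign)
  m <- x[[sign]]
  m[is.na(m)] <- 0
  k <- length(x$networks)
  graphics::image(seq_len(k), seq_len(k), m[, k:1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("Inter-network", sign, "edge density"), ...)
  graphics::axis(1, at = seq_len(k), labels = x$networks, las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(x$networks), las = 2)
  invisible(x)
}
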