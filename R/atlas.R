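#' Canonical network names
#'
#' The ten functional network labels used throughout the package, in their
#' conventional order: medial frontal (MF), fronto-parietal (FP), default
#' mode (DMN), motor (Mot), visual I (VI), visual II (VII), visual
#' association (VAs), limbic/salience (SAL), subcortical/basal ganglia (SC)
#' and cerebellum (CBL).
#'
#' @format Character vector of length 10.
#' @export
cpm_networks <- c("MF", "FP", "DMN", "Mot", "VI", "VII", "VAs", "SAL",
                  "SC", "CBL")

#' Construct an atlas from per-node network labels
#'
#' An atlas maps every node of a parcellation to exactly one functional
#' network. All edge-level summaries (inter-network tables, intra-network
#' heatmaps, association ratios) are defined relative to an atlas.
#'
#' @param labels Character vector, one network name per node.
#' @param networks Ordered set of valid network names. Defaults to the
#'   levels present in `labels`, in first-appearance order.
#' @param node_names Optional per-node anatomical names.
#' @return An object of class `cpm_atlas`: a data frame with columns
#'   `node` (1-based index) and `network` (factor), with the network order
#'   stored as factor levels.
#' @export
atlas <- function(labels, networks = NULL, node_names = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("an atlas needs at least 2 nodes")
  if (anyNA(labels)) stop("every node must have a network label")
  if (is.null(networks)) networks <- unique(labels)
  if (!all(labels %in% networks))
    stop("labels contain networks not in the declared network set: ",
         paste(setdiff(labels, networks), collapse = ", "))
  out <- data.frame(node = seq_along(labels),
                    network = factor(labels, levels = networks))
  if (!is.null(node_names)) {
    stopifnot(length(node_names) == length(labels))
    out$name <- as.character(node_names)
  }
  class(out) <- c("cpm_atlas", "data.frame")
  out
}

#' Synthetic block parcellation over the ten canonical networks
#'
#' Builds a stand-in atlas assigning contiguous blocks of nodes to the ten
#' canonical networks (see [cpm_networks]), with block sizes as equal as
#' possible. This is a synthetic parcellation for simulation and testing;
#' it shares only the node count and network vocabulary with real
#' 268-node functional atlases, not their anatomy.
#'
#' @param n_nodes Total node count (default 268).
#' @param networks Network names in order (default [cpm_networks]).
#' @return A `cpm_atlas`.
#' @examples
#' a <- synthetic_atlas(60)
#' table(a$network)
#' @export
synthetic_atlas <- function(n_nodes = 268L, networks = cpm_networks) {
  n_nodes <- as.integer(n_nodes)
  m <- length(networks)
  if (n_nodes < 2L * m)
    stop("need at least 2 nodes per network (", 2L * m, " total)")
  sizes <- rep(n_nodes %/% m, m)
  extra <- n_nodes %% m
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  atlas(rep(networks, times = sizes), networks = networks)
}

#' Number of nodes in an atlas
#' @param x A `cpm_atlas`.
#' @return Integer node count.
#' @export
n_nodes <- function(x) {
  stopifnot(inherits(x, "cpm_atlas"))
  nrow(x)
}

#' Node indices belonging to one network
#' @param atlas A `cpm_atlas`.
#' @param network Network name.
#' @return Integer vector of 1-based node indices.
#' @export
network_nodes <- function(atlas, network) {
  stopifnot(inherits(atlas, "cpm_atlas"))
  if (!network %in% levels(atlas$network))
    stop("unknown network: ", network)
  which(atlas$network == network)
}

#' Read / write an atlas as tab-separated text
#'
#' The file format is a two-column TSV with header `node_index` (0-based)
#' and `network_name`; an optional third column `node_name` carries
#' anatomical names. Round-tripping preserves labels and network order.
#'
#' @param path File path.
#' @return `read_atlas` returns a `cpm_atlas`; `write_atlas` returns
#'   `path` invisibly.
#' @export
read_atlas <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node_index", "network_name") %in% names(d)))
    stop("atlas file must have columns node_index, network_name")
  d <- d[order(d$node_index), ]
  if (!identical(as.integer(d$node_index), seq_len(nrow(d)) - 1L))
    stop("node_index must be 0-based and contiguous")
  atlas(d$network_name,
        node_names = if ("node_name" %in% names(d)) d$node_name else NULL)
}

#' @rdname read_atlas
#' @param atlas A `cpm_atlas` to write.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "cpm_atlas"))
  d <- data.frame(node_index = atlas$node - 1L,
                  network_name = as.character(atlas$network))
  if (!is.null(atlas$name)) d$node_name <- atlas$name
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cpm_atlas <- function(x, ...) {
  cat("Atlas:", nrow(x), "nodes,", nlevels(x$network), "networks\n")
  print(table(x$network))
  invisible(x)
}
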