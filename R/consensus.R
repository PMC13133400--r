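#' Consensus edges across LOOCV folds
#'
#' Edges selected in every fold of the cross-validation form the consensus
#' connectome — the reported predictive network.
#'
#' @param fold_masks list of integer edge-position vectors (one per fold),
#'   or the `fold_masks` component of a [cpm()] fit (then `modality` picks
#'   the entry).
#' @param modality modality name when `fold_masks` comes from a fit.
#' @return Sorted integer vector of edge positions; empty (with a warning)
#'   when the intersection is empty.
#' @export
consensus_edges <- function(fold_masks, modality = NULL) {
  if (!length(fold_masks)) stop("at least one fold mask required")
  if (!is.null(modality) || is.list(fold_masks[[1L]]))
    fold_masks <- lapply(fold_masks, `[[`,
                         if (is.null(modality)) 1L else modality)
  out <- sort(Reduce(intersect, fold_masks))
  if (!length(out)) warning("consensus connectome is empty")
  out
}

edge_endpoints <- function(edges, n_nodes) {
  idx <- edge_index(n_nodes)
  idx[edges, c("i", "j"), drop = FALSE]
}

#' Network distribution of a consensus connectome
#'
#' Summarizes an edge set by canonical network. Under the default
#' `"endpoint"` convention each edge contributes one count to each of its
#' two endpoint networks (one count total when both endpoints share a
#' network); a network's proportion is its count over the sum of all
#' counts. The `"within_double"` alternative counts a within-network edge
#' twice (once per endpoint), making proportions pure endpoint shares. The
#' unordered network-pair table is returned alongside for within-/
#' between-network statements.
#'
#' @param edges integer edge positions (e.g. from [consensus_edges()]).
#' @param atlas a [cpm_atlas()].
#' @param convention `"endpoint"` (default) or `"within_double"`.
#' @return List of class `network_distribution`: `counts` and
#'   `proportions` (named by network, proportions sum to 1), `pairs`
#'   (data frame network_a, network_b, n), `convention`.
#' @export
network_distribution <- function(edges, atlas,
                                 convention = c("endpoint", "within_double")) {
  convention <- match.arg(convention)
  stopifnot(inherits(atlas, "cpm_atlas"))
  ep <- edge_endpoints(edges, nrow(atlas))
  net_i <- atlas$network[ep$i]
  net_j <- atlas$network[ep$j]
  levels <- attr(atlas, "network_levels")
  counts <- stats::setNames(numeric(length(levels)), levels)
  for (k in seq_along(net_i)) {
    if (net_i[k] == net_j[k]) {
      counts[net_i[k]] <- counts[net_i[k]] +
        if (convention == "within_double") 2 else 1
    } else {
      counts[net_i[k]] <- counts[net_i[k]] + 1
      counts[net_j[k]] <- counts[net_j[k]] + 1
    }
  }
  a <- pmin(net_i, net_j)
  b <- pmax(net_i, net_j)
  pairs <- as.data.frame(table(network_a = a, network_b = b),
                         stringsAsFactors = FALSE)
  pairs <- pairs[pairs$Freq > 0, ]
  names(pairs)[3L] <- "n"
  rownames(pairs) <- NULL
  structure(list(counts = counts,
                 proportions = counts / sum(counts),
                 pairs = pairs, convention = convention),
            class = "network_distribution")
}

#' @export
print.network_distribution <- function(x, ...) {
  pr <- sort(x$proportions[x$proportions > 0], decreasing = TRUE)
  cat(sprintf("Network distribution (%s convention):\n", x$convention))
  for (nm in names(pr))
    cat(sprintf("  %-20s %5.1f%% (%g)\n", nm, 100 * pr[nm], x$counts[nm]))
  invisible(x)
}

#' Node degrees within a consensus connectome
#'
#' Degree = number of consensus edges incident to the node. Ties are broken
#' by node index; atlas labels and networks are attached.
#'
#' @param edges integer edge positions.
#' @param atlas a [cpm_atlas()].
#' @param top_k rows to return (clamped to the node count; default 20).
#' @return Data frame `node`, `label`, `network`, `degree`, sorted by
#'   decreasing degree.
#' @export
node_degree_table <- function(edges, atlas, top_k = 20L) {
  stopifnot(top_k >= 1L)
  n_nodes <- nrow(atlas)
  ep <- edge_endpoints(edges, n_nodes)
  deg <- tabulate(c(ep$i, ep$j), nbins = n_nodes)
  ord <- order(-deg, seq_len(n_nodes))
  out <- data.frame(node = ord, label = atlas$label[ord],
                    network = atlas$network[ord], degree = deg[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, min(top_k, n_nodes))
}

#' Consensus edge list with anatomical annotation
#'
#' Expands edge positions into the reporting table used for figure
#' regeneration: node indices, anatomical labels and network labels for
#' both endpoints.
#'
#' @param edges integer edge positions.
#' @param atlas a [cpm_atlas()].
#' @return Data frame `node_i`, `node_j`, `label_i`, `label_j`,
#'   `network_i`, `network_j`.
#' @export
consensus_edge_table <- function(edges, atlas) {
  ep <- edge_endpoints(edges, nrow(atlas))
  data.frame(node_i = ep$i, node_j = ep$j,
             label_i = atlas$label[ep$i], label_j = atlas$label[ep$j],
             network_i = atlas$network[ep$i],
             network_j = atlas$network[ep$j],
             stringsAsFactors = FALSE)
}
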