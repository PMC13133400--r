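#' Canonical network labels
#'
#' The ten canonical large-scale brain networks used to summarize consensus
#' connectomes (the grouping conventionally applied to the 268-node Shen
#' parcellation).
#'
#' @return Character vector of the ten network names.
#' @export
canonical_networks <- function() {
  c("medial frontal", "frontoparietal", "default mode", "motor",
    "visual I", "visual II", "visual association", "salience",
    "subcortical", "cerebellum")
}

#' Construct an atlas definition
#'
#' An atlas maps node indices (1-based) to anatomical labels, canonical
#' network labels, and optionally node volumes (mm^3). Every node carries
#' exactly one network label drawn from a closed set.
#'
#' @param networks character vector, one network label per node. Must be a
#'   subset of `levels` (default [canonical_networks()]).
#' @param labels optional per-node anatomical names; defaults to
#'   `node_<k>`.
#' @param volumes optional per-node volumes in mm^3, strictly positive.
#' @param levels the closed set of admissible network labels.
#' @return An object of class `cpm_atlas`: a data frame with columns
#'   `node`, `label`, `network` and optionally `volume_mm3`.
#' @examples
#' atl <- cpm_atlas(rep(canonical_networks()[1:5], each = 2))
#' nrow(atl)
#' @export
cpm_atlas <- function(networks, labels = NULL, volumes = NULL,
                      levels = canonical_networks()) {
  networks <- as.character(networks)
  n <- length(networks)
  if (n < 2L) stop("an atlas needs at least 2 nodes")
  bad <- setdiff(unique(networks), levels)
  if (length(bad))
    stop("unknown network label(s): ", paste(bad, collapse = ", "))
  if (is.null(labels)) labels <- sprintf("node_%d", seq_len(n))
  if (length(labels) != n) stop("labels length must match node count")
  atl <- data.frame(node = seq_len(n), label = as.character(labels),
                    network = networks, stringsAsFactors = FALSE)
  if (!is.null(volumes)) {
    volumes <- as.numeric(volumes)
    if (length(volumes) != n) stop("volumes length must match node count")
    if (any(!is.finite(volumes)) || any(volumes <= 0))
      stop("node volumes must be finite and strictly positive")
    atl$volume_mm3 <- volumes
  }
  attr(atl, "network_levels") <- levels
  class(atl) <- c("cpm_atlas", "data.frame")
  atl
}

#' Read an atlas table
#'
#' Delimited text with a header; columns `node` (1-based), `label`,
#' `network`, optional `volume_mm3`.
#'
#' @param path file path.
#' @param levels closed set of admissible network labels.
#' @return A [cpm_atlas()] object.
#' @export
read_atlas <- function(path, levels = canonical_networks()) {
  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           stringsAsFactors = FALSE)
  req <- c("node", "label", "network")
  if (!all(req %in% names(tab)))
    stop("atlas table must have columns: ", paste(req, collapse = ", "))
  tab <- tab[order(tab$node), ]
  if (!identical(as.integer(tab$node), seq_len(nrow(tab))))
    stop("atlas nodes must be 1..n without gaps")
  cpm_atlas(tab$network, labels = tab$label,
            volumes = if ("volume_mm3" %in% names(tab)) tab$volume_mm3,
            levels = levels)
}

#' Write an atlas table
#' @param atlas a [cpm_atlas()] object.
#' @param path output file path (CSV with header).
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# guess the field separator of a delimited text file from its first line
detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line, fixed = TRUE)) "," else ""
}
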