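#' Brain parcellation (node universe)
#'
#' A parcellation fixes the node set shared by every graph at a given
#' resolution: an ordered table of region-of-interest (ROI) identifiers and
#' anatomical labels. The multiresolution connectome atlases used in practice
#' come in 83, 129, 234, 463 and 1015 nodes, but any node count of at least
#' two is accepted.
#'
#' @param nodes Either a single integer `n` (nodes become `1:n` with generated
#'   labels) or a vector of positive integer node IDs, unique and strictly
#'   increasing.
#' @param labels Optional character vector of ROI labels, one per node.
#' @param resolution_name Text label for the resolution; defaults to
#'   `"scale<n>"`.
#'
#' @return An object of class `parcellation` with fields `resolution_name`
#'   and `nodes` (a data frame with columns `node_id`, `label`).
#' @examples
#' p <- parcellation(83)
#' p$resolution_name
#' @export
parcellation <- function(nodes, labels = NULL, resolution_name = NULL) {
  if (length(nodes) == 1L && is.null(labels) && is.numeric(nodes) && nodes > 1) {
    ids <- seq_len(as.integer(nodes))
  } else {
    ids <- as.integer(nodes)
  }
  if (length(ids) < 2L) {
    stop("a parcellation needs at least 2 nodes", call. = FALSE)
  }
  if (anyNA(ids) || any(ids < 1L)) {
    stop("node IDs must be positive integers", call. = FALSE)
  }
  if (is.unsorted(ids, strictly = TRUE)) {
    stop("node IDs must be unique and strictly increasing", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sprintf("roi_%04d", ids)
  }
  if (length(labels) != length(ids)) {
    stop("labels must have one entry per node", call. = FALSE)
  }
  if (is.null(resolution_name)) {
    resolution_name <- paste0("scale", length(ids))
  }
  structure(
    list(
      resolution_name = as.character(resolution_name),
      nodes = data.frame(
        node_id = ids,
        label = as.character(labels),
        stringsAsFactors = FALSE
      )
    ),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "<parcellation> %s: %d nodes (IDs %d..%d)\n",
    x$resolution_name, nrow(x$nodes),
    min(x$nodes$node_id), max(x$nodes$node_id)
  ))
  invisible(x)
}

# Two parcellations are interchangeable when the resolution name and the
# ordered node ID set agree; labels are metadata.
same_parcellation <- function(a, b) {
  identical(a$resolution_name, b$resolution_name) &&
    identical(a$nodes$node_id, b$nodes$node_id)
}

stopifnot_parcellation <- function(p) {
  if (!inherits(p, "parcellation")) {
    stop("expected a 'parcellation' object", call. = FALSE)
  }
  invisible(p)
}
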