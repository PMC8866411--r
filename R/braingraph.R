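#' Weighted braingraph
#'
#' One subject's undirected connectome: a map from unordered ROI pairs to a
#' positive fiber-count weight. Absence of an edge encodes weight zero, so no
#' zero-weight edge is ever stored. Edge keys are canonical
#' (`node1 < node2`) and rows are sorted, which makes serialized graphs
#' byte-stable.
#'
#' Weights are kept as doubles: raw tractography fiber counts are integers,
#' but trimmed-mean averaging produces fractional weights.
#'
#' @param edges A data frame with columns `node1`, `node2`, `weight` (or any
#'   three columns in that order), possibly empty or `NULL` for an edgeless
#'   graph. Rows may list either node first; they are canonicalized.
#' @param parcellation The [parcellation] the graph lives on; every endpoint
#'   must be one of its node IDs.
#' @param subject_id Subject identifier (text).
#' @param resolution_name Resolution label; defaults to the parcellation's.
#' @param drop_zero If `TRUE`, rows with weight exactly zero are dropped with
#'   a warning instead of raising an error (used when ingesting files).
#'
#' @return An object of class `braingraph` with fields `subject_id`,
#'   `resolution_name`, `parcellation` and `edges` (canonical, sorted data
#'   frame with columns `node1`, `node2`, `weight`).
#' @examples
#' p <- parcellation(5)
#' g <- braingraph(data.frame(node1 = c(2, 1), node2 = c(1, 3),
#'                            weight = c(14, 3)), p, "subj1")
#' edge_weight(g, 1, 2) # canonical lookup, order-insensitive
#' @export
braingraph <- function(edges, parcellation, subject_id,
                       resolution_name = parcellation$resolution_name,
                       drop_zero = FALSE) {
  stopifnot_parcellation(parcellation)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- empty_edge_df()
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 3L) {
      stop("edges need three columns: node1, node2, weight", call. = FALSE)
    }
    if (!all(c("node1", "node2", "weight") %in% names(edges))) {
      names(edges)[1:3] <- c("node1", "node2", "weight")
    }
    edges <- canonicalize_edges(edges, parcellation, subject_id,
                                drop_zero = drop_zero)
  }
  new_braingraph(edges, parcellation, subject_id, resolution_name)
}

# Fast internal constructor: `edges` must already be canonical and sorted.
new_braingraph <- function(edges, parcellation, subject_id, resolution_name) {
  structure(
    list(
      subject_id = as.character(subject_id),
      resolution_name = as.character(resolution_name),
      parcellation = parcellation,
      edges = edges
    ),
    class = "braingraph"
  )
}

empty_edge_df <- function() {
  data.frame(node1 = integer(0), node2 = integer(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

canonicalize_edges <- function(edges, parcellation, subject_id,
                               drop_zero = FALSE) {
  u <- as.integer(edges$node1)
  v <- as.integer(edges$node2)
  w <- as.numeric(edges$weight)
  if (anyNA(u) || anyNA(v) || anyNA(w)) {
    stop("malformed edge row: non-numeric node or weight", call. = FALSE)
  }
  if (any(u == v)) {
    bad <- u[u == v][1]
    stop(sprintf("self-loop on node %d in graph '%s'", bad, subject_id),
         call. = FALSE)
  }
  known <- parcellation$nodes$node_id
  unknown <- setdiff(c(u, v), known)
  if (length(unknown) > 0L) {
    stop(sprintf("node ID %d not in parcellation '%s'",
                 unknown[1], parcellation$resolution_name), call. = FALSE)
  }
  if (any(w == 0)) {
    if (drop_zero) {
      warning(sprintf("dropping %d zero-weight edge row(s) in graph '%s'",
                      sum(w == 0), subject_id), call. = FALSE)
      keep <- w != 0
      u <- u[keep]; v <- v[keep]; w <- w[keep]
    } else {
      stop(sprintf("zero-weight edge in graph '%s' (absence encodes weight 0)",
                   subject_id), call. = FALSE)
    }
  }
  if (any(w < 0)) {
    stop(sprintf("negative edge weight in graph '%s'", subject_id),
         call. = FALSE)
  }
  n1 <- pmin(u, v)
  n2 <- pmax(u, v)
  key <- paste(n1, n2)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate edge (%s) in graph '%s'",
                 gsub(" ", ",", dup), subject_id), call. = FALSE)
  }
  ord <- order(n1, n2)
  data.frame(node1 = n1[ord], node2 = n2[ord], weight = w[ord],
             stringsAsFactors = FALSE)
}

#' Number of edges of a braingraph
#' @param graph A `braingraph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) {
  nrow(graph$edges)
}

#' Edge weight lookup
#'
#' Returns the stored weight of the unordered pair `(u, v)`, or 0 when the
#' edge is absent. `edge_weight(g, u, v)` and `edge_weight(g, v, u)` are
#' identical by construction.
#'
#' @param graph A `braingraph`.
#' @param u,v Node IDs (vectors of equal length are allowed).
#' @return Numeric weight(s); 0 for absent edges.
#' @export
edge_weight <- function(graph, u, v) {
  key <- paste(pmin(u, v), pmax(u, v))
  idx <- match(key, paste(graph$edges$node1, graph$edges$node2))
  w <- graph$edges$weight[idx]
  w[is.na(w)] <- 0
  w
}

# Character keys "u v" (canonical) of the stored edges.
edge_key_set <- function(graph) {
  paste(graph$edges$node1, graph$edges$node2)
}

#' @export
print.braingraph <- function(x, ...) {
  cat(sprintf("<braingraph> subject %s, %s: %d edges\n",
              x$subject_id, x$resolution_name, nrow(x$edges)))
  invisible(x)
}
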