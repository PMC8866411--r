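#' Read a braingraph from a CSV edge list
#'
#' Expects a header `node1,node2,weight`, one edge per row, `#` comment
#' lines allowed. Rows may list either node first; keys are canonicalized to
#' `(min, max)`. A row whose canonical pair was already seen is an error.
#' Zero-weight rows are accepted and dropped with a warning (absence encodes
#' weight zero), matching how upstream pipelines occasionally emit them.
#'
#' @param path Path to the CSV file.
#' @param parcellation The [parcellation] the graph must live on.
#' @param subject_id Subject identifier to attach.
#' @param resolution_name Resolution label; defaults to the parcellation's.
#' @param delimiter Field separator, default `","`.
#' @return A [braingraph].
#' @export
read_edgelist <- function(path, parcellation, subject_id,
                          resolution_name = parcellation$resolution_name,
                          delimiter = ",") {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("numeric", "numeric", "numeric"))
  if (!identical(names(df), c("node1", "node2", "weight"))) {
    stop(sprintf("%s: expected header 'node1%snode2%sweight'",
                 path, delimiter, delimiter), call. = FALSE)
  }
  if (nrow(df) > 0 && any(df$node1 != floor(df$node1) |
                          df$node2 != floor(df$node2))) {
    stop(sprintf("%s: node columns must be integers", path), call. = FALSE)
  }
  braingraph(df, parcellation, subject_id, resolution_name, drop_zero = TRUE)
}

#' Write a braingraph as a CSV edge list
#'
#' Rows are emitted sorted by `(node1, node2)` ascending with weights
#' rendered at a fixed number of decimals, so identical graphs always produce
#' byte-identical files (diffable, hashable). An empty graph yields a
#' header-only file. `read_edgelist()` of the output recovers the graph up to
#' weight rounding.
#'
#' @param graph A [braingraph].
#' @param path Output path.
#' @param precision Decimals for the weight column (default 6).
#' @param delimiter Field separator, default `","`.
#' @return The path, invisibly.
#' @export
write_edgelist <- function(graph, path, precision = 6L, delimiter = ",") {
  e <- graph$edges
  header <- paste(c("node1", "node2", "weight"), collapse = delimiter)
  rows <- if (nrow(e) > 0) {
    paste(e$node1, e$node2,
          sprintf(paste0("%.", as.integer(precision), "f"), e$weight),
          sep = delimiter)
  } else {
    character(0)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a braingraph from GraphML
#'
#' Expects an undirected GraphML graph with an edge attribute `weight`,
#' vertex names holding the integer node IDs and (optionally) a vertex
#' attribute `label`, as produced by [write_graphml()]. Directed graphs and
#' edges lacking a weight are rejected.
#'
#' @param path Path to the GraphML file.
#' @param parcellation Optional [parcellation]; when omitted it is
#'   reconstructed from the file's vertex set.
#' @param subject_id Optional subject ID override (default: the file's
#'   `subject_id` graph attribute).
#' @return A [braingraph].
#' @export
read_graphml <- function(path, parcellation = NULL, subject_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) {
    stop(sprintf("%s: directed GraphML not supported (undirected only)", path),
         call. = FALSE)
  }
  if (!"weight" %in% igraph::edge_attr_names(g) && igraph::ecount(g) > 0) {
    stop(sprintf("%s: edges lack a 'weight' attribute", path), call. = FALSE)
  }
  vn <- igraph::vertex_attr(g, "name")
  if (is.null(vn)) {
    stop(sprintf("%s: vertices lack node IDs", path), call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(vn))
  if (anyNA(ids)) {
    stop(sprintf("%s: vertex names are not integer node IDs", path),
         call. = FALSE)
  }
  ga <- igraph::graph_attr(g)
  resolution <- if (!is.null(ga$resolution_name)) ga$resolution_name else NULL
  if (is.null(subject_id)) {
    subject_id <- if (!is.null(ga$subject_id)) ga$subject_id else "unknown"
  }
  if (is.null(parcellation)) {
    ord <- order(ids)
    labels <- igraph::vertex_attr(g, "label")
    if (is.null(labels)) labels <- sprintf("roi_%04d", ids)
    parcellation <- parcellation(ids[ord], labels[ord],
                                 resolution_name = resolution)
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(
    node1 = as.integer(el[, 1]),
    node2 = as.integer(el[, 2]),
    weight = if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  )
  if (anyNA(edges$weight)) {
    stop(sprintf("%s: edge with missing weight", path), call. = FALSE)
  }
  braingraph(edges, parcellation, subject_id,
             resolution_name = if (is.null(resolution))
               parcellation$resolution_name else resolution)
}

#' Write a braingraph as GraphML
#'
#' Emits a standard undirected GraphML document with every parcellation node
#' as a vertex (isolated ones included), integer node IDs as vertex names, a
#' `label` vertex attribute, a `weight` edge attribute, and `subject_id` /
#' `resolution_name` graph attributes. [read_graphml()] of the output
#' recovers the graph up to floating-point rounding.
#'
#' @param graph A [braingraph].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(graph, path) {
  nodes <- graph$parcellation$nodes
  vertices <- data.frame(name = as.character(nodes$node_id),
                         label = nodes$label, stringsAsFactors = FALSE)
  e <- graph$edges
  d <- data.frame(from = as.character(e$node1), to = as.character(e$node2),
                  weight = e$weight, stringsAsFactors = FALSE)
  ig <- igraph::graph_from_data_frame(d, directed = FALSE,
                                      vertices = vertices)
  ig <- igraph::set_graph_attr(ig, "subject_id", graph$subject_id)
  ig <- igraph::set_graph_attr(ig, "resolution_name", graph$resolution_name)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Deterministic name for an augmented graph
#'
#' `"<subject>_<resolution>_s<zero-padded index>"`, with the subset index
#' 0-based over the lexicographic subset order, e.g.
#' `101915_scale83_s000` .. `101915_scale83_s119` for the default 120-graph
#' augmentation.
#'
#' @param subject_id Subject identifier.
#' @param resolution_name Resolution label.
#' @param subset_index 0-based subset index, `0 <= subset_index < n_subsets`.
#' @param n_subsets Total subset count `choose(R, k)`; used for range
#'   checking (optional).
#' @param width Zero-padding width, default 3.
#' @return The name (no file extension).
#' @export
augmented_name <- function(subject_id, resolution_name, subset_index,
                           n_subsets = NULL, width = 3L) {
  idx <- as.integer(subset_index)
  if (is.na(idx) || idx < 0L) {
    stop("subset_index must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(n_subsets) && idx >= n_subsets) {
    stop(sprintf("subset_index %d out of range [0, %d)", idx, n_subsets),
         call. = FALSE)
  }
  sprintf("%s_%s_s%0*d", subject_id, resolution_name, as.integer(width), idx)
}
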