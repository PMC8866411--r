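#' Jaccard distance between the edge sets of two braingraphs
#'
#' `|symmetric difference| / |union|` of the two (unweighted) edge sets: the
#' fraction of edges in which the graphs differ. Weights are ignored. The
#' distance is a metric on edge sets: symmetric, zero iff the edge sets are
#' equal, bounded in `[0, 1]`, and satisfying the triangle inequality. When
#' both edge sets are empty the distance is defined as 0 (self-distance of
#' the empty graph), flagged with a message.
#'
#' @param g1,g2 [braingraph] objects over the same parcellation.
#' @return A number in `[0, 1]`.
#' @examples
#' p <- parcellation(5)
#' a <- braingraph(data.frame(node1 = 1, node2 = 2:4, weight = 1), p, "a")
#' b <- braingraph(data.frame(node1 = c(1, 1, 2), node2 = c(3, 4, 5),
#'                            weight = 1), p, "b")
#' jaccard_distance(a, b) # 2 differing edges / 4 in the union = 0.5
#' @export
jaccard_distance <- function(g1, g2) {
  if (!same_parcellation(g1$parcellation, g2$parcellation)) {
    stop("parcellation mismatch between graphs", call. = FALSE)
  }
  e1 <- edge_key_set(g1)
  e2 <- edge_key_set(g2)
  n_union <- length(union(e1, e2))
  if (n_union == 0L) {
    message("both edge sets empty; Jaccard distance defined as 0")
    return(0)
  }
  n_inter <- length(intersect(e1, e2))
  (n_union - n_inter) / n_union
}

#' Pairwise Jaccard distances partitioned into within/between classes
#'
#' Computes all unordered within-A ("red"), within-B ("blue") and across
#' ("green") Jaccard distances of two sets of graphs — the three-class
#' partition used to compare the spread of augmented graph sets. For two
#' augmented sets of 120 graphs each this is `choose(240, 2) = 28,680`
#' pairs: 7140 red, 7140 blue and 14,400 green.
#'
#' Internally the graphs are embedded as rows of a 0/1 edge-incidence matrix
#' over the union edge universe, and all pairwise intersection sizes are
#' obtained by one cross-product, so the quadratic pair count stays cheap.
#'
#' @param set_a,set_b Lists of [braingraph] objects (an [newtonian_blur()]
#'   `augmented_set` is accepted and its graphs used), all over one
#'   parcellation.
#' @return An object of class `pair_class_distances`: list with numeric
#'   fields `red`, `blue`, `green`.
#' @export
pairwise_class_distances <- function(set_a, set_b) {
  set_a <- as_graph_list(set_a)
  set_b <- as_graph_list(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both graph sets must be non-empty", call. = FALSE)
  }
  graphs <- c(set_a, set_b)
  p0 <- graphs[[1]]$parcellation
  for (g in graphs) {
    if (!same_parcellation(g$parcellation, p0)) {
      stop("parcellation mismatch across graph sets", call. = FALSE)
    }
  }
  keysets <- lapply(graphs, edge_key_set)
  universe <- unique(unlist(keysets, use.names = FALSE))
  n <- length(graphs)
  if (length(universe) == 0L) {
    J <- matrix(0, n, n)
  } else {
    M <- matrix(0L, nrow = n, ncol = length(universe))
    for (i in seq_len(n)) {
      M[i, match(keysets[[i]], universe)] <- 1L
    }
    inter <- tcrossprod(M)
    sizes <- rowSums(M)
    uni <- outer(sizes, sizes, "+") - inter
    J <- ifelse(uni > 0, 1 - inter / uni, 0)
  }
  na <- length(set_a)
  ia <- seq_len(na)
  ib <- seq_len(length(set_b)) + na
  upper <- function(m) m[upper.tri(m)]
  structure(
    list(
      red = upper(J[ia, ia, drop = FALSE]),
      blue = upper(J[ib, ib, drop = FALSE]),
      green = as.vector(J[ia, ib, drop = FALSE])
    ),
    class = "pair_class_distances"
  )
}

as_graph_list <- function(x) {
  if (inherits(x, "augmented_set")) return(x$graphs)
  if (inherits(x, "braingraph")) return(list(x))
  x
}

#' @export
print.pair_class_distances <- function(x, ...) {
  cat(sprintf(
    paste0("<pair_class_distances> %d red (mean %.4f), %d blue (mean %.4f),",
           " %d green (mean %.4f)\n"),
    length(x$red), mean(x$red), length(x$blue), mean(x$blue),
    length(x$green), mean(x$green)
  ))
  invisible(x)
}

#' Histogram of a distance list
#'
#' Left-closed right-open bins `[i*w, (i+1)*w)` starting at 0; a value
#' exactly on a bin edge belongs to the bin it starts. Counts sum to the
#' input length. Bins between 0 and the maximum observed bin are reported
#' contiguously (empty ones included). The default bin width 0.005 resolves
#' the narrow within-subject Jaccard peak.
#'
#' @param distances Numeric vector of non-negative distances.
#' @param bin_width Positive bin width.
#' @return A data frame with columns `bin_start`, `count` (zero rows for an
#'   empty input).
#' @export
distance_histogram <- function(distances, bin_width = 0.005) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number", call. = FALSE)
  }
  d <- as.numeric(distances)
  if (length(d) == 0L) {
    return(data.frame(bin_start = numeric(0), count = integer(0)))
  }
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  idx <- floor(d / bin_width)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  data.frame(bin_start = (seq_along(counts) - 1L) * bin_width,
             count = counts)
}

#' Plot the three-class Jaccard distance histogram
#'
#' Base-graphics rendering of the red/blue/green pair-distance classes as
#' overlaid histograms with a shared bin width.
#'
#' @param x A [pairwise_class_distances()] result.
#' @param bin_width Histogram bin width (default 0.005).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pair_class_distances <- function(x, bin_width = 0.005, ...) {
  hs <- list(red = distance_histogram(x$red, bin_width),
             blue = distance_histogram(x$blue, bin_width),
             green = distance_histogram(x$green, bin_width))
  xmax <- max(vapply(hs, function(h) max(h$bin_start), numeric(1))) + bin_width
  ymax <- max(vapply(hs, function(h) max(h$count), numeric(1)))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "Jaccard distance", ylab = "pair count", ...)
  for (cls in names(hs)) {
    h <- hs[[cls]]
    graphics::lines(h$bin_start + bin_width / 2, h$count, type = "h",
                    col = cls, lwd = 2)
  }
  graphics::legend("top", legend = c("within A", "within B", "across"),
                   col = c("red", "blue", "green"), lwd = 2, bty = "n")
  invisible(x)
}
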