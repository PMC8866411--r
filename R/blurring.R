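#' Enumerate k-subsets of run indices
#'
#' All `choose(R, k)` size-`k` subsets of the run indices `1..R`, in
#' lexicographic order. The ordering is the contract that makes augmented
#' output naming reproducible.
#'
#' @param R Ensemble size.
#' @param k Subset size, `1 <= k <= R`.
#' @return A list of `choose(R, k)` sorted integer vectors.
#' @examples
#' length(enumerate_subsets(10, 7)) # 120
#' enumerate_subsets(3, 2)          # (1,2), (1,3), (2,3)
#' @export
enumerate_subsets <- function(R, k) {
  R <- as.integer(R); k <- as.integer(k)
  if (is.na(R) || is.na(k) || k < 1L || k > R) {
    stop("need 1 <= k <= R", call. = FALSE)
  }
  # combn emits combinations of 1..R in lexicographic column order
  m <- utils::combn(R, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Edges surviving zero-filtering within a subset of runs
#'
#' The edges retained by the blurring workflow for one subset: exactly those
#' unordered node pairs whose weight is strictly positive in *every* run of
#' the subset. Runs outside the subset are ignored, so an edge that vanishes
#' only in unchosen runs survives.
#'
#' @param ensemble A validated [run_ensemble].
#' @param subset Integer vector of run indices (1-based).
#' @return A data frame with columns `node1`, `node2` (canonical, sorted).
#' @export
surviving_edges <- function(ensemble, subset) {
  subset <- as.integer(subset)
  if (anyNA(subset) || any(subset < 1L) || any(subset > length(ensemble$runs))) {
    stop("invalid run index in subset", call. = FALSE)
  }
  keys <- Reduce(intersect, lapply(ensemble$runs[subset], edge_key_set))
  if (length(keys) == 0L) {
    return(empty_edge_df()[, c("node1", "node2")])
  }
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(node1 = as.integer(parts[, 1]),
                    node2 = as.integer(parts[, 2]))
  out[order(out$node1, out$node2), , drop = FALSE]
}

#' Min/max-trimmed mean of a weight list
#'
#' Removes exactly `trim` occurrences of the largest and `trim` occurrences
#' of the smallest values — one occurrence per removal even under ties, so an
#' all-equal list of length k still loses 2·trim entries — and returns the
#' arithmetic mean of the remaining `k - 2*trim` values. The result always
#' lies in `[min(weights), max(weights)]`.
#'
#' @param weights Numeric vector of length k.
#' @param trim Occurrences removed per extreme; `k - 2*trim >= 1`.
#' @return The trimmed arithmetic mean.
#' @examples
#' trimmed_mean(c(1, 2, 3, 4, 5, 6, 7), 1) # 4: drop 1 and 7
#' trimmed_mean(rep(5, 7), 1)              # 5: ties lose one occurrence each
#' @export
trimmed_mean <- function(weights, trim = 1L) {
  w <- as.numeric(weights)
  trim <- as.integer(trim)
  k <- length(w)
  if (trim < 0L || k - 2L * trim < 1L) {
    stop(sprintf("cannot trim %d per side from %d weights", trim, k),
         call. = FALSE)
  }
  # remove one extreme occurrence per trim step, by index
  for (i in seq_len(trim)) {
    w <- w[-which.max(w)]
    w <- w[-which.min(w)]
  }
  # ascending summation order for a deterministic float result
  sum(sort(w)) / length(w)
}

# Row-wise trimmed means of a weight matrix (rows = edges, cols = the k
# subset runs). Fast closed form for trim == 1; generic sort for larger trim.
trimmed_row_means <- function(M, trim) {
  k <- ncol(M)
  if (k - 2L * trim < 1L) {
    stop("too few weights for the trim level", call. = FALSE)
  }
  if (nrow(M) == 0L) return(numeric(0))
  if (trim == 0L) return(rowMeans(M))
  if (trim == 1L) {
    cols <- lapply(seq_len(k), function(j) M[, j])
    (rowSums(M) - do.call(pmax, cols) - do.call(pmin, cols)) / (k - 2L)
  } else {
    apply(M, 1L, function(x) {
      s <- sort(x)
      sum(s[(trim + 1L):(k - trim)]) / (k - 2L * trim)
    })
  }
}

# Union edge table of an ensemble plus the edges-by-runs weight matrix
# (0 encodes absence). Shared by newtonian_blur and basic_average.
ensemble_weight_matrix <- function(ensemble) {
  tabs <- lapply(ensemble$runs, function(g) g$edges)
  all_pairs <- unique(do.call(rbind, lapply(tabs, function(e) {
    e[, c("node1", "node2"), drop = FALSE]
  })))
  all_pairs <- all_pairs[order(all_pairs$node1, all_pairs$node2), ,
                         drop = FALSE]
  rownames(all_pairs) <- NULL
  key <- paste(all_pairs$node1, all_pairs$node2)
  W <- matrix(0, nrow = nrow(all_pairs), ncol = length(ensemble$runs))
  for (r in seq_along(tabs)) {
    e <- tabs[[r]]
    W[match(paste(e$node1, e$node2), key), r] <- e$weight
  }
  list(pairs = all_pairs, W = W)
}

#' Newtonian blurring of a run ensemble
#'
#' The augmentation workflow: for each of the `choose(R, k)` subsets of the
#' runs (lexicographic order), delete every edge that has weight 0 (is
#' absent) in at least one chosen run, then assign each surviving edge the
#' min/max-trimmed mean of its k subset weights. One graph per subset, so a
#' 10-run ensemble at the default `(10, 7, 1)` yields 120 augmented graphs.
#'
#' No artificial component is introduced: every output weight is a trimmed
#' average of actually observed weights, and every output edge was observed
#' in all chosen runs.
#'
#' @param ensemble A [run_ensemble] with `config$R` runs.
#' @param config An [aug_config]; default `(10, 7, 1)`.
#' @return An object of class `augmented_set` with fields `subject_id`,
#'   `resolution_name`, `config`, `subsets` (list of index vectors) and
#'   `graphs` (list of [braingraph], parallel to `subsets`).
#' @seealso [basic_average()] for the one-graph consensus variant.
#' @export
newtonian_blur <- function(ensemble, config = aug_config()) {
  ensemble <- validate_ensemble(ensemble, config)
  subsets <- enumerate_subsets(config$R, config$k)
  ew <- ensemble_weight_matrix(ensemble)
  graphs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    Ws <- ew$W[, s, drop = FALSE]
    keep <- rowSums(Ws > 0) == config$k
    wt <- trimmed_row_means(Ws[keep, , drop = FALSE], config$trim)
    edges <- ew$pairs[keep, , drop = FALSE]
    edges$weight <- wt
    rownames(edges) <- NULL
    graphs[[i]] <- new_braingraph(edges, ensemble$parcellation,
                                  ensemble$subject_id,
                                  ensemble$resolution_name)
  }
  structure(
    list(
      subject_id = ensemble$subject_id,
      resolution_name = ensemble$resolution_name,
      config = config,
      subsets = subsets,
      graphs = graphs
    ),
    class = "augmented_set"
  )
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf(
    "<augmented_set> subject %s, %s: %d graphs from (R=%d, k=%d, trim=%d)\n",
    x$subject_id, x$resolution_name, length(x$graphs),
    x$config$R, x$config$k, x$config$trim
  ))
  invisible(x)
}

#' Basic averaging of a run ensemble
#'
#' The one-graph consensus strategy: keep only edges with a nonzero weight in
#' all R runs, delete each edge's minimum and maximum weight, and average the
#' remaining R - 2 weights. Equivalent to [newtonian_blur()] with
#' configuration `(R, k = R, trim = 1)`, which produces exactly one graph.
#'
#' @param ensemble A [run_ensemble] with at least 3 runs.
#' @return A single consensus [braingraph].
#' @export
basic_average <- function(ensemble) {
  if (!inherits(ensemble, "run_ensemble")) {
    stop("expected a 'run_ensemble' object", call. = FALSE)
  }
  R <- length(ensemble$runs)
  if (R < 3L) {
    stop("basic averaging needs at least 3 runs", call. = FALSE)
  }
  ensemble <- validate_ensemble(ensemble, aug_config(R, R, 1L))
  ew <- ensemble_weight_matrix(ensemble)
  keep <- rowSums(ew$W > 0) == R
  edges <- ew$pairs[keep, , drop = FALSE]
  # direct per-edge sort-and-slice; deliberately not the blur fast path
  edges$weight <- apply(ew$W[keep, , drop = FALSE], 1L, function(x) {
    s <- sort(x)
    sum(s[2:(R - 1L)]) / (R - 2L)
  })
  if (nrow(edges) == 0L) edges <- empty_edge_df()
  rownames(edges) <- NULL
  new_braingraph(edges, ensemble$parcellation, ensemble$subject_id,
                 ensemble$resolution_name)
}

#' Closed-form edge survival count
#'
#' The number of augmented graphs that contain an edge whose weight is zero
#' in exactly `zero_runs` of the R runs: `choose(R - zero_runs, k)` when
#' `k <= R - zero_runs`, otherwise 0. At the default `(10, 7)` an edge
#' present in all runs survives in all 120 graphs; an edge missing from one
#' run survives in `choose(9, 7) = 36` and is deleted from the
#' `choose(9, 6) = 84` subsets that include the zero run (the two counts
#' adding to 120 by the Pascal-triangle identity).
#'
#' @param zero_runs Number of runs in which the edge is absent, `0..R`.
#' @param config An [aug_config].
#' @return Integer count in `0..choose(R, k)`.
#' @examples
#' edge_survival_count(0) # 120
#' edge_survival_count(1) # 36
#' edge_survival_count(4) # 0
#' @export
edge_survival_count <- function(zero_runs, config = aug_config()) {
  z <- as.integer(zero_runs)
  if (is.na(z) || z < 0L || z > config$R) {
    stop(sprintf("zero_runs must lie in 0..%d", config$R), call. = FALSE)
  }
  if (config$k > config$R - z) {
    return(0L)
  }
  as.integer(round(choose(config$R - z, config$k)))
}
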