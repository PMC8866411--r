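# Shared fixture builders: everything is generated in code at test time.

# Quick graph: edges given as a 3-column matrix/data.frame (node1, node2, weight).
bg <- function(edges, parc, subject = "s1", ...) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 3, byrow = TRUE)
  edges <- as.data.frame(edges)
  names(edges) <- c("node1", "node2", "weight")
  braingraph(edges, parc, subject, ...)
}

# A random ensemble built directly (independently of the synthetic_data
# module): each candidate edge gets a positive weight per run with
# probability p_present, weight 0 (absent) otherwise.
random_ensemble <- function(R = 10, n_nodes = 8, p_present = 0.8,
                            seed = 1, subject = "s1") {
  set.seed(seed)
  parc <- parcellation(n_nodes)
  pairs <- t(utils::combn(n_nodes, 2))
  runs <- lapply(seq_len(R), function(r) {
    present <- stats::runif(nrow(pairs)) < p_present
    edges <- data.frame(node1 = pairs[present, 1], node2 = pairs[present, 2],
                        weight = round(stats::runif(sum(present), 1, 100)))
    braingraph(edges, parc, subject)
  })
  run_ensemble(runs)
}

# Ensemble with fully controlled per-edge weight profiles: `profiles` is a
# named list mapping "u v" -> length-R weight vector (0 = absent in that run).
profile_ensemble <- function(profiles, n_nodes = 10, subject = "s1") {
  R <- length(profiles[[1]])
  parc <- parcellation(n_nodes)
  pairs <- do.call(rbind, strsplit(names(profiles), " ", fixed = TRUE))
  runs <- lapply(seq_len(R), function(r) {
    w <- vapply(profiles, `[`, numeric(1), r)
    keep <- w > 0
    braingraph(data.frame(node1 = as.integer(pairs[keep, 1]),
                          node2 = as.integer(pairs[keep, 2]),
                          weight = w[keep]),
               parc, subject)
  })
  run_ensemble(runs)
}

expect_same_graph <- function(g1, g2, tolerance = 1e-12) {
  expect_equal(g1$edges$node1, g2$edges$node1)
  expect_equal(g1$edges$node2, g2$edges$node2)
  expect_equal(g1$edges$weight, g2$edges$weight, tolerance = tolerance)
}
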