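test_that("enumerate_subsets yields all k-subsets in lexicographic order", {
  s <- enumerate_subsets(3, 2)
  expect_equal(s, list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_equal(enumerate_subsets(5, 5), list(1:5))
  expect_length(enumerate_subsets(10, 7), 120)

  s107 <- enumerate_subsets(10, 7)
  expect_false(any(duplicated(s107)))
  # lexicographic: each tuple sorted, successive tuples strictly increasing
  expect_true(all(vapply(s107, function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
  keys <- vapply(s107, function(x) paste(sprintf("%02d", x), collapse = ""),
                 character(1))
  expect_false(is.unsorted(keys, strictly = TRUE))

  expect_error(enumerate_subsets(5, 6), "k <= R")
  expect_error(enumerate_subsets(5, 0), "k <= R")
})

test_that("trimmed_mean matches a sort-and-slice oracle incl. ties", {
  # frozen worked examples
  expect_equal(trimmed_mean(c(1, 2, 3, 4, 5, 6, 7), 1), 4)
  expect_equal(trimmed_mean(rep(5, 7), 1), 5)
  expect_equal(trimmed_mean(c(2, 2, 9, 9, 9, 1, 10), 1), 31 / 5)
  expect_error(trimmed_mean(c(1, 2), 1), "cannot trim")

  oracle <- function(w, trim) {
    s <- sort(w)
    mean(s[(trim + 1):(length(s) - trim)])
  }
  set.seed(99)
  for (i in 1:200) {
    k <- sample(3:12, 1)
    trim <- sample(0:((k - 1) %/% 2), 1)
    w <- if (i %% 3 == 0) {
      sample(1:4, k, replace = TRUE) # heavy ties
    } else {
      round(stats::runif(k, 0, 50), 2)
    }
    expect_equal(trimmed_mean(w, trim), oracle(w, trim), tolerance = 1e-12)
    expect_gte(trimmed_mean(w, trim), min(w))
    expect_lte(trimmed_mean(w, trim), max(w))
  }
})

test_that("surviving_edges keeps exactly the everywhere-positive subset edges", {
  # edge "1 2": in all runs; "1 3": missing from run 2; "2 3": missing from 5
  prof <- list("1 2" = c(5, 6, 7, 8, 9), "1 3" = c(4, 0, 4, 4, 4),
               "2 3" = c(2, 2, 2, 2, 0))
  ens <- profile_ensemble(prof, n_nodes = 4)

  s134 <- surviving_edges(ens, c(1, 3, 4)) # avoids both zero runs
  expect_equal(paste(s134$node1, s134$node2), c("1 2", "1 3", "2 3"))
  s125 <- surviving_edges(ens, c(1, 2, 5)) # hits both zero runs
  expect_equal(paste(s125$node1, s125$node2), "1 2")

  expect_error(surviving_edges(ens, c(1, 6)), "invalid run index")

  empty <- profile_ensemble(list("1 2" = c(0, 0, 0)), n_nodes = 3)
  expect_equal(nrow(surviving_edges(empty, 1:3)), 0L)
})

test_that("newtonian_blur matches brute-force subset enumeration", {
  for (seed in c(1, 2, 3)) {
    R <- 7; k <- 5
    ens <- random_ensemble(R = R, n_nodes = 6, p_present = 0.7, seed = seed)
    cfg <- aug_config(R, k, 1)
    aug <- newtonian_blur(ens, cfg)
    subsets <- utils::combn(R, k)
    expect_length(aug$graphs, choose(R, k))

    # brute force: recompute every subset graph edge-by-edge
    pairs <- t(utils::combn(6, 2))
    for (j in seq_len(ncol(subsets))) {
      s <- subsets[, j]
      expect_equal(aug$subsets[[j]], s)
      g <- aug$graphs[[j]]
      for (e in seq_len(nrow(pairs))) {
        w <- vapply(ens$runs[s], edge_weight, numeric(1),
                    u = pairs[e, 1], v = pairs[e, 2])
        expected <- if (all(w > 0)) trimmed_mean(w, 1) else 0
        expect_equal(edge_weight(g, pairs[e, 1], pairs[e, 2]), expected,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("per-edge survival counts follow the binomial closed form", {
  cfg <- aug_config(10, 7, 1)
  expect_equal(edge_survival_count(0, cfg), 120L)
  expect_equal(edge_survival_count(1, cfg), 36L)
  expect_equal(edge_survival_count(3, cfg), 1L)
  expect_equal(edge_survival_count(4, cfg), 0L)
  expect_error(edge_survival_count(11, cfg), "0..10")

  # Pascal identity: subsets containing a fixed zero run + survivors = total
  expect_equal(edge_survival_count(1, cfg) + choose(9, 6), choose(10, 7))

  # oracle equivalence on a random ensemble: presence count over the
  # augmented set equals C(R - z, k) for each edge's zero-run count z
  ens <- random_ensemble(R = 8, n_nodes = 6, p_present = 0.75, seed = 11)
  cfg2 <- aug_config(8, 5, 1)
  aug <- newtonian_blur(ens, cfg2)
  pairs <- t(utils::combn(6, 2))
  for (e in seq_len(nrow(pairs))) {
    z <- sum(vapply(ens$runs, edge_weight, numeric(1),
                    u = pairs[e, 1], v = pairs[e, 2]) == 0)
    count <- sum(vapply(aug$graphs, function(g) {
      edge_weight(g, pairs[e, 1], pairs[e, 2]) > 0
    }, logical(1)))
    expect_equal(count, edge_survival_count(z, cfg2))
  }
})

test_that("blurring an ensemble of identical runs reproduces the input", {
  p <- parcellation(5)
  g <- bg(rbind(c(1, 2, 10), c(2, 3, 4), c(4, 5, 7)), p)
  ens <- run_ensemble(rep(list(g), 10))
  aug <- newtonian_blur(ens)
  expect_length(aug$graphs, 120)
  for (out in aug$graphs[c(1, 60, 120)]) expect_same_graph(out, g)
  expect_same_graph(basic_average(ens), g)
})

test_that("basic_average equals the single graph of (R, R, 1) blurring", {
  expect_error(basic_average(random_ensemble(R = 2, seed = 1)),
               "at least 3")
  # frozen worked example: drop 1 and 100, average eight 10s
  prof <- list("1 2" = c(10, 10, 10, 10, 10, 10, 10, 10, 1, 100),
               "1 3" = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 0))
  ens <- profile_ensemble(prof, n_nodes = 3)
  avg <- basic_average(ens)
  expect_equal(edge_weight(avg, 1, 2), 10)
  expect_equal(edge_weight(avg, 1, 3), 0) # absent in one run -> deleted

  for (seed in c(4, 5)) {
    ens <- random_ensemble(R = 6, n_nodes = 7, p_present = 0.8, seed = seed)
    one <- newtonian_blur(ens, aug_config(6, 6, 1))
    expect_length(one$graphs, 1)
    expect_same_graph(basic_average(ens), one$graphs[[1]])
  }
})

test_that("trimmed means are monotone in any single run weight", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(3:9, 1)
    w <- stats::runif(k, 1, 50)
    j <- sample(k, 1)
    w2 <- w
    w2[j] <- w[j] + stats::runif(1, 0, 20)
    expect_gte(trimmed_mean(w2, 1), trimmed_mean(w, 1) - 1e-12)
  }
})

test_that("augmented weights stay within the subset's weight range", {
  ens <- random_ensemble(R = 6, n_nodes = 5, p_present = 0.9, seed = 8)
  cfg <- aug_config(6, 4, 1)
  aug <- newtonian_blur(ens, cfg)
  for (j in seq_along(aug$graphs)) {
    g <- aug$graphs[[j]]
    s <- aug$subsets[[j]]
    for (e in seq_len(nrow(g$edges))) {
      w <- vapply(ens$runs[s], edge_weight, numeric(1),
                  u = g$edges$node1[e], v = g$edges$node2[e])
      expect_gte(g$edges$weight[e], min(w) - 1e-12)
      expect_lte(g$edges$weight[e], max(w) + 1e-12)
    }
  }
})
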