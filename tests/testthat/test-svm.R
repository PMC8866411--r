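toy_problem <- function(n = 30, seed = 5, margin_noise = 0.4) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n), n, 2)
  y <- ifelse(x[, 1] + margin_noise * stats::rnorm(n) > 0, 1L, -1L)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(x = x, y = y)
}

test_that("graph_to_features flattens the upper triangle in pair order", {
  p <- parcellation(83)
  empty <- braingraph(NULL, p, "e")
  f <- graph_to_features(empty)
  expect_length(f, 3403) # 83 * 82 / 2
  expect_true(all(f == 0))

  single <- bg(c(1, 2, 9), p, "s")
  fs <- graph_to_features(single)
  expect_equal(which(fs == 1L), 1L) # (1,2) is the first pair

  p4 <- parcellation(4)
  g <- bg(rbind(c(2, 3, 1), c(3, 4, 1)), p4, "g")
  # order: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  expect_equal(graph_to_features(g), c(0L, 0L, 0L, 1L, 0L, 1L))

  pairs <- t(utils::combn(4, 2))
  complete <- bg(cbind(pairs, 1), p4, "c")
  expect_true(all(graph_to_features(complete) == 1L))

  expect_error(graph_to_features(g, p), "parcellation mismatch")
})

test_that("scale_penalty divides by the fold", {
  expect_equal(scale_penalty(1, 120), 1 / 120)
  expect_equal(scale_penalty(2.5, 1), 2.5)
  expect_error(scale_penalty(0, 10), "positive")
  expect_error(scale_penalty(-1, 10), "positive")
  expect_error(scale_penalty(1, 0), "fold")
})

test_that("train_linear_svm separates a separable toy and validates input", {
  x <- matrix(c(-1, 1), 2, 1)
  y <- c(-1L, 1L)
  fit <- train_linear_svm(x, y, C = 100)
  expect_gt(fit$w[1], 0)
  expect_equal(predict(fit, x), y)

  expect_error(train_linear_svm(x, c(1L, 1L), 1), "single class")
  expect_error(train_linear_svm(x, y, 0), "positive")
  expect_error(train_linear_svm(x, c(1L, 2L), 1), "\\+1/-1")
})

test_that("duplicating points 120x at C/120 reproduces the solution at C", {
  toy <- toy_problem(n = 20, seed = 3)
  f1 <- train_linear_svm(toy$x, toy$y, C = 1, tolerance = 1e-9)
  rep_idx <- rep(seq_len(nrow(toy$x)), each = 120)
  f2 <- train_linear_svm(toy$x[rep_idx, ], toy$y[rep_idx],
                         scale_penalty(1, 120), tolerance = 1e-9)
  expect_lt(max(abs(c(f1$w - f2$w, f1$b - f2$b))), 1e-6)
})

test_that("solver objective is no worse than a brute-force grid search", {
  objective <- function(w, b, x, y, C) {
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(x %*% w) + b)))
  }
  toy <- toy_problem(n = 16, seed = 11)
  C <- 0.5
  fit <- train_linear_svm(toy$x, toy$y, C, tolerance = 1e-9)
  obj_fit <- objective(fit$w, fit$b, toy$x, toy$y, C)

  gr <- seq(-3, 3, by = 0.05)
  best <- Inf
  for (w1 in gr) for (w2 in gr) {
    f0 <- toy$x %*% c(w1, w2)
    for (b in seq(-2, 2, by = 0.1)) {
      o <- 0.5 * (w1^2 + w2^2) + C * sum(pmax(0, 1 - toy$y * (f0 + b)))
      if (o < best) best <- o
    }
  }
  expect_lte(obj_fit, best + 1e-6)
})

test_that("dcd solver minimizes its regularized-bias objective", {
  # the dcd path regularizes the intercept (appended constant feature), so
  # its objective is 1/2 (|w|^2 + b^2) + C sum hinge; verify optimality
  # against a brute-force grid on a 2-D toy
  toy <- toy_problem(n = 16, seed = 11)
  C <- 0.5
  fit <- dcd_linear_svm(toy$x, toy$y, C, tolerance = 1e-9,
                        max_epochs = 200000)
  obj <- function(w1, w2, b) {
    0.5 * (w1^2 + w2^2 + b^2) +
      C * sum(pmax(0, 1 - toy$y * (drop(toy$x %*% c(w1, w2)) + b)))
  }
  obj_fit <- obj(fit$w[1], fit$w[2], fit$b)
  gr <- seq(-3, 3, by = 0.05)
  best <- Inf
  for (w1 in gr) for (w2 in gr) {
    f0 <- toy$x %*% c(w1, w2)
    for (b in seq(-2, 2, by = 0.1)) {
      o <- 0.5 * (w1^2 + w2^2 + b^2) +
        C * sum(pmax(0, 1 - toy$y * (f0 + b)))
      if (o < best) best <- o
    }
  }
  expect_lte(obj_fit, best + 1e-6)
})

test_that("dcd and libsvm solutions agree up to bias-regularization effects", {
  for (seed in c(2, 9)) {
    toy <- toy_problem(n = 60, seed = seed)
    for (C in c(0.05, 1, 20)) {
      ref <- train_linear_svm(toy$x, toy$y, C, tolerance = 1e-8)
      dcd <- dcd_linear_svm(toy$x, toy$y, C, tolerance = 1e-8,
                            max_epochs = 200000)
      # same separating direction; identical labels on nearly all points
      cosine <- sum(ref$w * dcd$w) /
        sqrt(sum(ref$w^2) * sum(dcd$w^2))
      expect_gt(cosine, 0.99)
      expect_gte(mean(predict(dcd, toy$x) == predict(ref, toy$x)), 0.95)
    }
  }
})

test_that("collapsing duplicated rows into multiplicities is exact", {
  toy <- toy_problem(n = 25, seed = 13)
  mult <- sample(1:5, 25, replace = TRUE)
  idx <- rep(seq_len(25), times = mult)
  full <- dcd_linear_svm(toy$x[idx, ], toy$y[idx], C = 0.3,
                         tolerance = 1e-9, max_epochs = 200000)
  deduped <- dcd_linear_svm(toy$x, toy$y, C = 0.3,
                            instance_multiplicity = mult,
                            tolerance = 1e-9, max_epochs = 200000)
  expect_lt(max(abs(c(full$w - deduped$w, full$b - deduped$b))), 1e-6)
})

test_that("stratified split preserves class balance at the subject level", {
  labels <- c(rep(1L, 567), rep(-1L, 486)) # 1053 subjects
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_length(sp$train, 737)
  expect_length(sp$test, 316)
  expect_equal(sum(labels[sp$train] == 1L), 397)
  expect_equal(sum(labels[sp$test] == 1L), 170)
  expect_length(intersect(sp$train, sp$test), 0)
  # reproducible
  expect_identical(sp, stratified_split(labels, 0.7, seed = 1))
})

test_that("experiment keeps subject-level separation and valid accuracies", {
  cfg <- synthetic_cohort_config(16, n_nodes = 12, seed = 41)
  coh <- generate_cohort(cfg)
  res <- augmentation_experiment(coh, aug_config(10, 7, 1),
                                 grid = c(-1, 1), seed = 41)
  expect_s3_class(res, "experiment_result")
  expect_equal(res$log10_C, c(-1, 1))
  acc <- unlist(res[, -1])
  expect_true(all(acc >= 0 & acc <= 1))
  expect_equal(attr(res, "fold"), 120L)
  expect_equal(attr(res, "n_train") + attr(res, "n_test"), 16)
})

test_that("degenerate blur config (R, R, 1) collapses the two arms", {
  cfg <- synthetic_cohort_config(12, n_nodes = 10, seed = 43)
  coh <- generate_cohort(cfg)
  res <- augmentation_experiment(coh, aug_config(10, 10, 1),
                                 grid = c(-1, 0, 1), seed = 43)
  expect_equal(attr(res, "fold"), 1L)
  # one identical graph per subject in both arms, fold 1: identical results
  expect_equal(res$test_aug, res$test_plain, tolerance = 1e-8)
  expect_equal(res$train_aug, res$train_plain, tolerance = 1e-8)
})
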