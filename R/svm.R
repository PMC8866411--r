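#' Binary edge-indicator feature vector of a braingraph
#'
#' Flattens the upper triangle of the adjacency indicator into a 0/1 vector
#' of length `n*(n-1)/2` in fixed lexicographic pair order
#' `(1,2), (1,3), ..., (1,n), (2,3), ...` over the parcellation node IDs, so
#' feature positions are comparable across graphs. This is the 0-1 weighted
#' representation used for classification; fiber counts are ignored.
#'
#' @param graph A [braingraph].
#' @param parcellation The [parcellation] fixing the node order; defaults to
#'   the graph's own.
#' @return An integer 0/1 vector of length `n*(n-1)/2`.
#' @export
graph_to_features <- function(graph, parcellation = graph$parcellation) {
  stopifnot_parcellation(parcellation)
  if (!same_parcellation(graph$parcellation, parcellation)) {
    stop("parcellation mismatch", call. = FALSE)
  }
  ids <- parcellation$nodes$node_id
  n <- length(ids)
  x <- integer(n * (n - 1L) / 2L)
  if (nrow(graph$edges) > 0L) {
    u <- match(graph$edges$node1, ids)
    v <- match(graph$edges$node2, ids)
    # lexicographic upper-triangle position of pair (u, v), u < v
    pos <- (u - 1L) * n - (u * (u + 1L)) %/% 2L + v
    x[pos] <- 1L
  }
  x
}

feature_matrix <- function(graphs, parcellation) {
  t(vapply(graphs, graph_to_features, integer(
    nrow(parcellation$nodes) * (nrow(parcellation$nodes) - 1L) / 2L
  ), parcellation = parcellation))
}

#' Rescale the SVM penalty for an augmented training set
#'
#' When every training point is replaced by `fold` augmented copies, the
#' soft-margin objective `1/2 w.w + C * sum(z_i)` accumulates `fold` slack
#' terms per original point; using `C / fold` restores the scale of the
#' objective, and with exact copies the optimum `(w, b)` is unchanged. For
#' the default 120-fold augmentation this is the `C / 120` rule.
#'
#' @param C Original penalty, positive.
#' @param fold Augmentation fold (number of copies per original point).
#' @return `C / fold`.
#' @export
scale_penalty <- function(C, fold) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("C must be a positive number", call. = FALSE)
  }
  fold <- as.integer(fold)
  if (is.na(fold) || fold < 1L) {
    stop("fold must be a positive integer", call. = FALSE)
  }
  C / fold
}

#' Train a linear soft-margin SVM
#'
#' Minimizes `1/2 w.w + C * sum(z_i)` subject to
#' `y_i (w.x_i + b) >= 1 - z_i`, `z_i >= 0`, and predicts by
#' `sign(w.x + b)`. The convex optimization is delegated to the libsvm
#' backend of \pkg{e1071}; this wrapper pins down the primal
#' parameterization and returns the explicit hyperplane.
#'
#' @param x Numeric feature matrix, one row per training point.
#' @param y Labels, +1/-1, one per row of `x`.
#' @param C Penalty for margin violations, positive.
#' @param tolerance Solver termination tolerance (default 1e-3; tighten for
#'   high-precision comparisons).
#' @return An object of class `linear_svm`: list with the weight vector `w`,
#'   intercept `b`, penalty `C`, and the underlying model.
#' @export
train_linear_svm <- function(x, y, C, tolerance = 1e-3) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (C <= 0) stop("C must be positive", call. = FALSE)
  fit <- e1071::svm(x = x, y = factor(y, levels = c(-1L, 1L)),
                    type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision function toward the first class it sees;
  # re-orient so that sign(w.x + b) reproduces the model's own predictions
  f <- drop(x %*% w) + b
  pred <- as.integer(as.character(stats::predict(fit, x)))
  nz <- which(f != 0)
  if (length(nz) > 0 && mean(sign(f[nz]) == pred[nz]) < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, C = C, model = fit), class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, x, ...) {
  f <- drop(as.matrix(x) %*% object$w) + object$b
  ifelse(f >= 0, 1L, -1L)
}

svm_accuracy <- function(model, x, y) {
  mean(predict(model, x) == y)
}

#' Large-scale linear SVM via dual coordinate descent
#'
#' The fast linear path used for the augmentation experiment: hinge-loss
#' linear SVM solved by dual coordinate descent in the style of LIBLINEAR,
#' with the intercept carried as an appended constant feature (so the bias is
#' part of the regularized weight vector, as in LIBLINEAR and scikit-learn's
#' `LinearSVC`). Supports per-instance costs, which lets exactly duplicated
#' training rows be collapsed without changing the optimum: `m` identical
#' points at cost `C` are equivalent to one point at cost `m * C` because
#' hinge slacks of identical points add.
#'
#' For the exact unregularized-intercept formulation use
#' [train_linear_svm()]; the two agree closely whenever the intercept is
#' small relative to the margin.
#'
#' @param x Numeric feature matrix, one row per point.
#' @param y Labels +1/-1.
#' @param C Penalty, positive.
#' @param instance_multiplicity Optional positive multiplicities, one per
#'   row; row `i` counts as that many copies.
#' @param tolerance Projected-gradient stopping tolerance (default 1e-4).
#' @param max_epochs Epoch cap (default 2000).
#' @param bias_scale Value of the appended intercept feature (default 1).
#' @return A `linear_svm` object (fields `w`, `b`, `C`).
#' @export
dcd_linear_svm <- function(x, y, C, instance_multiplicity = NULL,
                           tolerance = 1e-4, max_epochs = 2000L,
                           bias_scale = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (is.null(instance_multiplicity)) {
    ci <- rep(C, nrow(x))
  } else {
    if (length(instance_multiplicity) != nrow(x) ||
        any(instance_multiplicity <= 0)) {
      stop("instance_multiplicity must be positive, one per row",
           call. = FALSE)
    }
    ci <- C * as.numeric(instance_multiplicity)
  }
  csr <- dense_to_csr(x)
  fit <- dcd_svm_fit(csr$row_ptr, csr$col_idx, csr$val, nrow(x), ncol(x),
                     y, ci, tolerance, as.integer(max_epochs),
                     bias_scale, 987654321L)
  structure(list(w = fit$w, b = fit$b, C = C, converged = fit$converged,
                 epochs = fit$epochs),
            class = "linear_svm")
}

# 0-based compressed sparse row view of a dense matrix.
dense_to_csr <- function(x) {
  nz <- which(t(x) != 0)  # row-major order
  col0 <- as.integer((nz - 1L) %% ncol(x))
  row <- (nz - 1L) %/% ncol(x) + 1L
  counts <- tabulate(row, nbins = nrow(x))
  list(
    row_ptr = c(0L, cumsum(counts)),
    col_idx = col0,
    val = as.numeric(t(x))[nz]
  )
}

# Collapse exactly duplicated feature rows (within label) into unique rows
# with multiplicities.
collapse_duplicates <- function(x, y) {
  key <- do.call(paste, c(as.data.frame(cbind(y, x)), sep = "\r"))
  first_idx <- which(!duplicated(key))
  grp <- match(key, key[first_idx])
  mult <- tabulate(grp, nbins = length(first_idx))
  list(x = x[first_idx, , drop = FALSE], y = y[first_idx],
       multiplicity = mult)
}

#' Stratified subject-level train/test split
#'
#' Samples `round(train_fraction * n_c)` training subjects within each label
#' class, so the class balance of the cohort carries over to both halves.
#' A 1053-subject cohort at fraction 0.7 gives the 737 / 316 split shape.
#'
#' @param labels Vector of +1/-1 subject labels.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed for the draw.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  idx <- seq_along(labels)
  with_seed(seed, {
    train <- unlist(lapply(unique(labels), function(cl) {
      members <- idx[labels == cl]
      sample(members, round(train_fraction * length(members)))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(idx, train))
}

#' Augmented-vs-plain linear SVM experiment
#'
#' Reproduces the augmentation experiment design on a labeled cohort:
#' subjects (never individual graphs) are split into train and test. The
#' plain arm trains on one basic-average consensus graph per training
#' subject at penalty `C`; the augmented arm trains on all `choose(R, k)`
#' blurred graphs per training subject at the rescaled penalty
#' `C / choose(R, k)`. Both arms are evaluated on the identical test set of
#' basic-average graphs — augmented graphs of test subjects are never used,
#' which is asserted. Features are the binary edge indicators of
#' [graph_to_features()]; the penalty grid is swept on a log10 scale.
#'
#' @param cohort A [generate_cohort()] result (or any list with `ensembles`,
#'   `labels`, `parcellation`).
#' @param blur_config [aug_config] for the augmented arm.
#' @param grid Numeric vector of log10(C) values (default -4..2 by 0.5).
#' @param train_fraction Fraction of each class used for training.
#' @param seed Seed for the subject split.
#' @param solver `"dcd"` (default; the [dcd_linear_svm()] linear path with
#'   duplicated augmented rows collapsed exactly into instance costs) or
#'   `"libsvm"` (the [train_linear_svm()] reference solver; much slower on
#'   the fold-expanded training set).
#' @param svm_tolerance Solver tolerance.
#' @return An object of class `experiment_result`: data frame with columns
#'   `log10_C`, `train_plain`, `test_plain`, `train_aug`, `test_aug`, with
#'   attributes `n_train`, `n_test`, `fold`.
#' @export
augmentation_experiment <- function(cohort,
                                    blur_config = aug_config(),
                                    grid = seq(-4, 2, by = 0.5),
                                    train_fraction = 0.7,
                                    seed = 1L,
                                    solver = c("dcd", "libsvm"),
                                    svm_tolerance = NULL) {
  solver <- match.arg(solver)
  if (is.null(svm_tolerance)) {
    svm_tolerance <- if (solver == "dcd") 1e-4 else 1e-3
  }
  labels <- as.integer(cohort$labels)
  if (sum(labels == 1L) < 2L || sum(labels == -1L) < 2L) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  parc <- cohort$parcellation
  split <- stratified_split(labels, train_fraction, seed)
  if (length(unique(labels[split$train])) < 2L ||
      length(split$test) < 1L) {
    stop("degenerate train/test split", call. = FALSE)
  }

  avg_graphs <- lapply(cohort$ensembles, basic_average)
  x_all <- feature_matrix(avg_graphs, parc)
  x_train <- x_all[split$train, , drop = FALSE]
  y_train <- labels[split$train]
  x_test <- x_all[split$test, , drop = FALSE]
  y_test <- labels[split$test]

  # augmented arm: blur training subjects only (test leakage is structurally
  # impossible, and asserted)
  fold <- as.integer(round(choose(blur_config$R, blur_config$k)))
  aug_feats <- vector("list", length(split$train))
  aug_subjects <- character(0)
  for (i in seq_along(split$train)) {
    s <- split$train[i]
    aug <- newtonian_blur(cohort$ensembles[[s]], blur_config)
    aug_feats[[i]] <- feature_matrix(aug$graphs, parc)
    aug_subjects <- c(aug_subjects, aug$subject_id)
  }
  test_subjects <- vapply(cohort$ensembles[split$test],
                          function(e) e$subject_id, character(1))
  stopifnot(length(intersect(aug_subjects, test_subjects)) == 0L)
  x_aug <- do.call(rbind, aug_feats)
  y_aug <- rep(y_train, each = fold)
  if (solver == "dcd") {
    dedup <- collapse_duplicates(x_aug, y_aug)
  }

  fit_svm <- function(x, y, C, multiplicity = NULL) {
    if (solver == "dcd") {
      dcd_linear_svm(x, y, C, instance_multiplicity = multiplicity,
                     tolerance = svm_tolerance)
    } else {
      train_linear_svm(x, y, C, tolerance = svm_tolerance)
    }
  }
  rows <- lapply(grid, function(g) {
    C <- 10^g
    plain <- fit_svm(x_train, y_train, C)
    aug <- if (solver == "dcd") {
      fit_svm(dedup$x, dedup$y, scale_penalty(C, fold),
              multiplicity = dedup$multiplicity)
    } else {
      fit_svm(x_aug, y_aug, scale_penalty(C, fold))
    }
    data.frame(
      log10_C = g,
      train_plain = svm_accuracy(plain, x_train, y_train),
      test_plain = svm_accuracy(plain, x_test, y_test),
      train_aug = svm_accuracy(aug, x_aug, y_aug),
      test_aug = svm_accuracy(aug, x_test, y_test)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_train") <- length(split$train)
  attr(out, "n_test") <- length(split$test)
  attr(out, "fold") <- fold
  class(out) <- c("experiment_result", class(out))
  out
}
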