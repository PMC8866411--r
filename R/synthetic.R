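#' Configuration for the synthetic tractography cohort generator
#'
#' Defines a generative model that emulates the statistical structure of a
#' repeated-tractography braingraph dataset: a population-level backbone of
#' candidate edges shared by all subjects, per-subject latent graphs drawn
#' from the backbone, and per-run detection noise that makes every
#' tractography run a slightly different graph. A designated subset of
#' backbone edges carries a weak class signal (edge-presence shift for
#' class +1 subjects), mirroring a binary label with a weak structural
#' correlate.
#'
#' Defaults are calibrated so that, after Newtonian blurring, within-subject
#' augmented-graph Jaccard distances sit a few percent above zero while
#' between-subject distances are several-fold larger — the qualitative
#' within/between separation observed on real repeated-tractography data.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Parcellation size (default 83).
#' @param runs_per_subject Tractography repetitions per subject (default 10).
#' @param backbone_density Fraction of node pairs that are population-level
#'   candidate edges, in `(0, 1]`.
#' @param subject_edge_prob Probability a backbone edge exists in a given
#'   subject's latent graph, in `(0, 1]`.
#' @param detection_prob Per-run probability that an existing latent edge is
#'   detected with a nonzero fiber count, in `(0, 1]`.
#' @param mean_fibers Mean of the per-edge latent fiber count (positive).
#' @param fiber_dispersion Log-scale standard deviation of the latent fiber
#'   means (log-normal), positive.
#' @param class_effect Additive shift of `subject_edge_prob` on the
#'   designated signal edges for class +1 subjects (non-negative).
#' @param class_fraction Fraction of subjects labeled +1, in `[0, 1]`.
#' @param run_weight_noise `"poisson"` (zero-truncated Poisson counts around
#'   the latent mean) or `"none"` (deterministic `max(1, round(mean))`).
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_subjects,
                                    n_nodes = 83L,
                                    runs_per_subject = 10L,
                                    backbone_density = 0.3,
                                    subject_edge_prob = 0.5,
                                    detection_prob = 0.99,
                                    mean_fibers = 30,
                                    fiber_dispersion = 0.8,
                                    class_effect = 0.1,
                                    class_fraction = 0.5,
                                    run_weight_noise = c("poisson", "none"),
                                    seed = 1L) {
  run_weight_noise <- match.arg(run_weight_noise)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_nodes = as.integer(n_nodes),
    runs_per_subject = as.integer(runs_per_subject),
    backbone_density = backbone_density,
    subject_edge_prob = subject_edge_prob,
    detection_prob = detection_prob,
    mean_fibers = mean_fibers,
    fiber_dispersion = fiber_dispersion,
    class_effect = class_effect,
    class_fraction = class_fraction,
    run_weight_noise = run_weight_noise,
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$n_nodes < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  if (cfg$runs_per_subject < 1L) {
    stop("runs_per_subject must be >= 1", call. = FALSE)
  }
  in_unit <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (!in_unit(cfg$backbone_density)) {
    stop("backbone_density must be in (0, 1]", call. = FALSE)
  }
  if (!in_unit(cfg$subject_edge_prob)) {
    stop("subject_edge_prob must be in (0, 1]", call. = FALSE)
  }
  if (!in_unit(cfg$detection_prob)) {
    stop("detection_prob must be in (0, 1]", call. = FALSE)
  }
  if (cfg$mean_fibers <= 0) stop("mean_fibers must be > 0", call. = FALSE)
  if (cfg$fiber_dispersion <= 0) {
    stop("fiber_dispersion must be > 0", call. = FALSE)
  }
  if (cfg$class_effect < 0) stop("class_effect must be >= 0", call. = FALSE)
  if (cfg$class_fraction < 0 || cfg$class_fraction > 1) {
    stop("class_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synthetic_cohort_config")
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Keeps cohort generation independent of ambient state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Per-subject substream seed: deterministic in (master seed, subject index,
# stream offset), independent of generation order. Kept below 2^31.
substream_seed <- function(config, subject_index, stream = 0L) {
  as.integer(
    (as.numeric(config$seed %% 65521L) * 29303 +
       as.numeric(subject_index) * 7 + stream) %% 2147483647
  )
}

# Population backbone: candidate node pairs shared by all subjects, plus the
# designated class-signal subset (a fixed 10% of the backbone). Deterministic
# in the master seed alone.
backbone_pairs <- function(config) {
  n <- config$n_nodes
  pairs <- utils::combn(n, 2L)
  n_pairs <- ncol(pairs)
  n_bb <- max(1L, round(config$backbone_density * n_pairs))
  with_seed(substream_seed(config, 0L, 1L), {
    sel <- sort(sample.int(n_pairs, n_bb))
    signal <- rep(FALSE, n_bb)
    signal[sample.int(n_bb, max(1L, round(0.1 * n_bb)))] <- TRUE
    data.frame(node1 = pairs[1L, sel], node2 = pairs[2L, sel],
               signal = signal)
  })
}

cohort_parcellation <- function(config) {
  parcellation(config$n_nodes)
}

#' Sample one subject's latent braingraph
#'
#' Includes each backbone candidate edge independently with
#' `subject_edge_prob` (shifted up by `class_effect` on the designated signal
#' edges when `label == 1`), and assigns each included edge a latent mean
#' fiber count drawn log-normally with mean `mean_fibers` and log-sd
#' `fiber_dispersion`. Deterministic given `(seed, subject_index, label)`.
#'
#' @param config A [synthetic_cohort_config].
#' @param subject_index 1-based subject index.
#' @param label Class label, +1 or -1.
#' @return A [braingraph] whose weights are the latent mean fiber counts.
#' @export
sample_latent_graph <- function(config, subject_index, label = -1L) {
  if (!label %in% c(-1L, 1L)) stop("label must be +1 or -1", call. = FALSE)
  bb <- backbone_pairs(config)
  parc <- cohort_parcellation(config)
  subject_id <- sprintf("subj%04d", subject_index)
  with_seed(substream_seed(config, subject_index, 2L), {
    p <- rep(config$subject_edge_prob, nrow(bb))
    if (label == 1L) {
      p[bb$signal] <- pmin(1, p[bb$signal] + config$class_effect)
    }
    incl <- stats::runif(nrow(bb)) < p
    sdlog <- config$fiber_dispersion
    mu <- log(config$mean_fibers) - sdlog^2 / 2
    edges <- bb[incl, c("node1", "node2"), drop = FALSE]
    edges$weight <- stats::rlnorm(sum(incl), meanlog = mu, sdlog = sdlog)
    braingraph(edges, parc, subject_id)
  })
}

# Zero-truncated Poisson draws via inverse-CDF, vectorized over lambda.
rtrunc_pois <- function(lambda) {
  p0 <- stats::ppois(0, lambda)
  u <- stats::runif(length(lambda), min = p0, max = 1)
  pmax(1L, stats::qpois(u, lambda))
}

#' Sample a run ensemble around a latent graph
#'
#' Produces `runs_per_subject` tractography-like runs: each latent edge is
#' detected in a run independently with `detection_prob`, and a detected
#' edge gets an integer fiber count of at least 1 drawn around its latent
#' mean (zero-truncated Poisson, or the rounded mean when
#' `run_weight_noise = "none"`). Edges outside the latent graph never appear.
#'
#' @param latent A latent [braingraph] from [sample_latent_graph()].
#' @param config A [synthetic_cohort_config].
#' @param subject_index 1-based subject index (fixes the noise substream).
#' @return A [run_ensemble].
#' @export
sample_run_ensemble <- function(latent, config, subject_index) {
  n_e <- nrow(latent$edges)
  lam <- latent$edges$weight
  with_seed(substream_seed(config, subject_index, 3L), {
    runs <- lapply(seq_len(config$runs_per_subject), function(r) {
      detected <- stats::runif(n_e) < config$detection_prob
      counts <- if (config$run_weight_noise == "poisson") {
        rtrunc_pois(lam)
      } else {
        pmax(1, round(lam))
      }
      edges <- latent$edges[detected, c("node1", "node2"), drop = FALSE]
      edges$weight <- as.numeric(counts[detected])
      rownames(edges) <- NULL
      new_braingraph(edges, latent$parcellation, latent$subject_id,
                     latent$resolution_name)
    })
    run_ensemble(runs)
  })
}

#' Generate a labeled synthetic cohort
#'
#' `n_subjects` run ensembles with binary labels: the first
#' `ceiling(class_fraction * n_subjects)` subjects are labeled +1, the rest
#' -1. Fully reproducible from the config seed; each subject's randomness
#' comes from a substream keyed by the subject index, so individual subjects
#' are stable regardless of how many others are generated.
#'
#' @param config A [synthetic_cohort_config].
#' @return An object of class `labeled_cohort`: list with `ensembles` (list
#'   of [run_ensemble]), `labels` (integer +1/-1), `parcellation`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_cohort_config")) {
    stop("expected a 'synthetic_cohort_config'", call. = FALSE)
  }
  n <- config$n_subjects
  n_pos <- ceiling(config$class_fraction * n)
  labels <- c(rep(1L, n_pos), rep(-1L, n - n_pos))
  ensembles <- lapply(seq_len(n), function(i) {
    latent <- sample_latent_graph(config, i, labels[i])
    sample_run_ensemble(latent, config, i)
  })
  structure(
    list(
      ensembles = ensembles,
      labels = labels,
      parcellation = cohort_parcellation(config),
      config = config
    ),
    class = "labeled_cohort"
  )
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf(
    "<labeled_cohort> %d subjects (%d labeled +1), %d runs each, %s\n",
    length(x$ensembles), sum(x$labels == 1L),
    x$config$runs_per_subject, x$parcellation$resolution_name
  ))
  invisible(x)
}
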