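#' Augmentation configuration
#'
#' The three integers governing subset enumeration and trimming: `R` repeated
#' runs per subject, subsets of size `k`, and `trim` weight occurrences
#' removed from each extreme before averaging. The production defaults are
#' `(R = 10, k = 7, trim = 1)`: every 7-subset of the 10 runs is zero-filtered,
#' its min and max weights dropped, and the remaining 5 averaged. Basic
#' averaging corresponds to `(R, k = R, trim = 1)`.
#'
#' @param R Ensemble size (positive integer).
#' @param k Subset size, `1 <= k <= R`.
#' @param trim Occurrences removed per extreme; `k - 2 * trim >= 1`.
#' @return An object of class `aug_config`.
#' @examples
#' aug_config()          # (10, 7, 1): 120 augmented graphs per subject
#' aug_config(10, 10, 1) # basic averaging
#' @export
aug_config <- function(R = 10L, k = 7L, trim = 1L) {
  R <- as.integer(R); k <- as.integer(k); trim <- as.integer(trim)
  if (anyNA(c(R, k, trim)) || R < 1L || k < 1L || trim < 0L) {
    stop("R and k must be positive integers, trim non-negative", call. = FALSE)
  }
  if (k > R) {
    stop(sprintf("subset size k = %d exceeds ensemble size R = %d", k, R),
         call. = FALSE)
  }
  if (k - 2L * trim < 1L) {
    stop(sprintf("trim = %d leaves no weight out of k = %d after trimming",
                 trim, k), call. = FALSE)
  }
  structure(list(R = R, k = k, trim = trim), class = "aug_config")
}

#' @export
print.aug_config <- function(x, ...) {
  cat(sprintf("<aug_config> R = %d, k = %d, trim = %d (%d subsets)\n",
              x$R, x$k, x$trim, choose(x$R, x$k)))
  invisible(x)
}

#' Run ensemble
#'
#' The ordered list of `R` weighted braingraphs obtained by repeating the
#' probabilistic tractography pipeline on one subject at one resolution.
#' Run order is significant and preserved.
#'
#' @param runs List of [braingraph] objects sharing subject, resolution and
#'   parcellation.
#' @return An object of class `run_ensemble` with fields `subject_id`,
#'   `resolution_name`, `parcellation`, `runs`.
#' @export
run_ensemble <- function(runs) {
  if (!is.list(runs) || length(runs) < 1L) {
    stop("an ensemble needs at least one run", call. = FALSE)
  }
  if (!all(vapply(runs, inherits, logical(1), "braingraph"))) {
    stop("all runs must be braingraph objects", call. = FALSE)
  }
  first <- runs[[1]]
  for (i in seq_along(runs)) {
    g <- runs[[i]]
    if (!identical(g$subject_id, first$subject_id)) {
      stop(sprintf("run %d has subject '%s', expected '%s'",
                   i, g$subject_id, first$subject_id), call. = FALSE)
    }
    if (!identical(g$resolution_name, first$resolution_name) ||
        !same_parcellation(g$parcellation, first$parcellation)) {
      stop(sprintf("run %d has a different parcellation/resolution", i),
           call. = FALSE)
    }
  }
  structure(
    list(
      subject_id = first$subject_id,
      resolution_name = first$resolution_name,
      parcellation = first$parcellation,
      runs = runs
    ),
    class = "run_ensemble"
  )
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf("<run_ensemble> subject %s, %s: %d runs\n",
              x$subject_id, x$resolution_name, length(x$runs)))
  invisible(x)
}

#' Validate a run ensemble against an augmentation configuration
#'
#' Checks every type invariant — run count equal to `config$R`, shared
#' parcellation, no self-loops, strictly positive weights — and
#' re-canonicalizes edge keys. Validation is idempotent: validating twice
#' yields an identical object.
#'
#' @param ensemble A [run_ensemble].
#' @param config An [aug_config].
#' @return The validated (canonicalized) ensemble.
#' @export
validate_ensemble <- function(ensemble, config = aug_config()) {
  if (!inherits(ensemble, "run_ensemble")) {
    stop("expected a 'run_ensemble' object", call. = FALSE)
  }
  if (!inherits(config, "aug_config")) {
    stop("expected an 'aug_config' object", call. = FALSE)
  }
  if (length(ensemble$runs) != config$R) {
    stop(sprintf("expected %d runs, found %d",
                 config$R, length(ensemble$runs)), call. = FALSE)
  }
  runs <- vector("list", config$R)
  for (i in seq_along(ensemble$runs)) {
    g <- ensemble$runs[[i]]
    if (!same_parcellation(g$parcellation, ensemble$parcellation)) {
      stop(sprintf("run %d: parcellation mismatch", i), call. = FALSE)
    }
    runs[[i]] <- tryCatch(
      braingraph(g$edges, ensemble$parcellation, g$subject_id,
                 g$resolution_name),
      error = function(e) {
        stop(sprintf("run %d: %s", i, conditionMessage(e)), call. = FALSE)
      }
    )
  }
  out <- ensemble
  out$runs <- runs
  out
}
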