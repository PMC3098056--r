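# Permutation significance baseline for MI(class; feature).
#
# Class labels are repeatedly shuffled, every feature is re-discretized by
# MI maximization against the shuffled labels, and the largest "random" MI
# over all features and permutations becomes the baseline. An empirical
# multiplier (default 3.2) converts the baseline into the significance
# threshold used for feature selection: the MI-maximizing discretization
# inflates null MI values, so the raw permutation maximum alone admits far
# too many features.

#' Significance threshold specification
#'
#' @param baseline_mi largest MI (bits) observed under class-label
#'   permutation.
#' @param multiplier dimensionless factor applied to the baseline
#'   (default 3.2).
#' @param n_perm,seed optional provenance fields recorded for reporting.
#' @return object of class `threshold_spec` with fields `baseline_mi`,
#'   `multiplier` and `effective_threshold = baseline_mi * multiplier`.
#' @export
threshold_spec <- function(baseline_mi, multiplier = 3.2, n_perm = NA_integer_,
                           seed = NA_integer_) {
  if (baseline_mi < 0) stop("`baseline_mi` must be non-negative")
  if (multiplier <= 0) stop("`multiplier` must be positive")
  structure(list(baseline_mi = baseline_mi, multiplier = multiplier,
                 effective_threshold = baseline_mi * multiplier,
                 n_perm = n_perm, seed = seed),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "MI significance threshold: %.5f bits (baseline %.5f x multiplier %.2f",
    x$effective_threshold, x$baseline_mi, x$multiplier))
  if (!is.na(x$n_perm)) cat(", ", x$n_perm, " permutations", sep = "")
  cat(")\n")
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Permutation baseline for the MI significance threshold
#'
#' The table is first discretized by MI maximization against the true
#' labels. For each of `n_perm` permutations the class labels are then
#' shuffled and `MI(shuffled class; binned feature)` is computed on that
#' fixed discretization; the maximum over all features and all
#' permutations is the baseline, and the effective threshold is
#' `baseline * multiplier`. Because the bins are frozen, the baseline does
#' not include the inflation introduced by boundary maximization — that
#' bias is what the empirical multiplier (default 3.2) absorbs. Setting
#' `rediscretize = TRUE` instead re-optimizes every feature's boundaries
#' against each shuffled labeling, giving a (much larger) baseline that
#' already contains the maximization bias.
#'
#' @param tbl a [sample_table()].
#' @param n_perm number of label permutations (default 100).
#' @param multiplier significance multiplier (default 3.2).
#' @param seed integer seed; the result is deterministic given the seed and
#'   the caller's RNG state is left untouched.
#' @param exhaustive_cap,n_candidates discretizer settings, see
#'   [discretize_max_mi()].
#' @param disc optional precomputed [discretize_table()] result for `tbl`
#'   (ignored when `rediscretize = TRUE`).
#' @param rediscretize re-run the boundary optimization inside every
#'   permutation (default `FALSE`).
#' @return a [threshold_spec()].
#' @export
permutation_baseline <- function(tbl, n_perm = 100L, multiplier = 3.2,
                                 seed = 1L, exhaustive_cap = 64L,
                                 n_candidates = 64L, disc = NULL,
                                 rediscretize = FALSE) {
  stopifnot(inherits(tbl, "sample_table"))
  if (n_perm < 1L) stop("`n_perm` must be at least 1")
  x <- tbl$abundances
  labels <- tbl$class_labels
  n <- nrow(x)
  nclass <- length(unique(labels))
  baseline <- 0
  if (rediscretize) {
    with_local_seed(seed, {
      for (p in seq_len(n_perm)) {
        lp <- labels[sample.int(n)]
        for (j in seq_len(ncol(x))) {
          mi <- discretize_max_mi(x[, j], lp, exhaustive_cap = exhaustive_cap,
                                  n_candidates = n_candidates)$mi
          if (mi > baseline) baseline <- mi
        }
      }
    })
  } else {
    if (is.null(disc)) {
      disc <- discretize_table(tbl, exhaustive_cap = exhaustive_cap,
                               n_candidates = n_candidates)
    }
    bins <- disc$bins
    codes <- as_codes(labels)$codes
    with_local_seed(seed, {
      for (p in seq_len(n_perm)) {
        cp <- codes[sample.int(n)]
        for (j in seq_len(ncol(bins))) {
          mi <- fast_mi(cp, bins[, j], nclass, 3L)
          if (mi > baseline) baseline <- mi
        }
      }
    })
  }
  threshold_spec(baseline, multiplier = multiplier, n_perm = as.integer(n_perm),
                 seed = as.integer(seed))
}
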