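#' Method settings
#'
#' A single configuration block for the pipeline, with the defaults used
#' throughout: 100 label permutations, significance multiplier 3.2,
#' conditional-MI drop threshold 0.75, consensus frequency threshold 0.5,
#' deterministic decision threshold 0.5, Laplace pseudocount 1.
#'
#' @param n_perm permutations for the significance baseline.
#' @param multiplier significance multiplier applied to the permutation
#'   baseline.
#' @param drop_threshold fractional conditional-MI drop (in (0,1)) that
#'   demotes a first-level feature to a child.
#' @param freq_threshold consensus arc-frequency threshold.
#' @param decision_threshold posterior probability above which the positive
#'   class is called.
#' @param pseudocount Laplace smoothing count for the conditional
#'   probability tables.
#' @param exhaustive_cap,n_candidates discretizer grid settings, see
#'   [discretize_max_mi()].
#' @param recompute_threshold recompute the permutation baseline inside
#'   each cross-validation fold instead of once on the full table
#'   (default `FALSE`).
#' @param multi_parent allow child features to keep several parents
#'   (default `FALSE`: single strongest parent).
#' @param seed integer seed for the permutation baseline when computed
#'   implicitly.
#' @return a list of class `bn_settings`.
#' @export
bn_settings <- function(n_perm = 100L, multiplier = 3.2, drop_threshold = 0.75,
                        freq_threshold = 0.5, decision_threshold = 0.5,
                        pseudocount = 1, exhaustive_cap = 64L,
                        n_candidates = 64L, recompute_threshold = FALSE,
                        multi_parent = FALSE, seed = 1L) {
  stopifnot(n_perm >= 1L, multiplier > 0, drop_threshold > 0,
            drop_threshold < 1, freq_threshold > 0, freq_threshold < 1,
            decision_threshold >= 0, decision_threshold <= 1,
            pseudocount >= 0)
  structure(list(n_perm = as.integer(n_perm), multiplier = multiplier,
                 drop_threshold = drop_threshold,
                 freq_threshold = freq_threshold,
                 decision_threshold = decision_threshold,
                 pseudocount = pseudocount,
                 exhaustive_cap = as.integer(exhaustive_cap),
                 n_candidates = as.integer(n_candidates),
                 recompute_threshold = recompute_threshold,
                 multi_parent = multi_parent,
                 seed = as.integer(seed)),
            class = "bn_settings")
}
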