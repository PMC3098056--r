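# End-to-end analysis: permutation threshold -> repeated CV -> consensus
# network -> frozen classifier.

#' Run the full stability analysis on a peak table
#'
#' Computes the permutation significance threshold, runs repeated
#' stratified k-fold cross-validation recording every fold's network, builds
#' the consensus network of arcs appearing in more than `freq_threshold` of
#' the recorded networks, and fits the final classifier on the full table
#' (rediscretized on all cases) restricted to the consensus first-level
#' features.
#'
#' @param tbl a [sample_table()].
#' @param plan a [cv_plan()].
#' @param settings a [bn_settings()].
#' @return list of class `bn_analysis`: `report` (stability report),
#'   `consensus` (a [bn_net()]), `classifier` (a frozen
#'   [fit_parameters()] object), `threshold`.
#' @export
run_stability_analysis <- function(tbl, plan = cv_plan(),
                                   settings = bn_settings()) {
  report <- run_cv(tbl, plan, settings)
  consensus <- build_consensus(report, freq_threshold = settings$freq_threshold)
  classifier <- train_frozen_classifier(tbl, consensus, settings)
  structure(list(report = report, consensus = consensus,
                 classifier = classifier, threshold = report$threshold),
            class = "bn_analysis")
}

#' @export
print.bn_analysis <- function(x, ...) {
  print(x$report)
  print(x$consensus)
  invisible(x)
}

#' Fit the final classifier for a fixed network on the full table
#'
#' The entire table is rediscretized (boundaries re-optimized on all
#' cases) and smoothed conditional probability tables are estimated for
#' the network's first-level features; the resulting boundaries and tables
#' are frozen into the classifier.
#'
#' @param tbl a [sample_table()].
#' @param net a [bn_net()] (typically the consensus network).
#' @param settings a [bn_settings()].
#' @param positive_class see [fit_parameters()].
#' @return a frozen `bn_classifier`.
#' @export
train_frozen_classifier <- function(tbl, net, settings = bn_settings(),
                                    positive_class = NULL) {
  disc <- discretize_table(tbl, exhaustive_cap = settings$exhaustive_cap,
                           n_candidates = settings$n_candidates)
  fit_parameters(net, disc, pseudocount = settings$pseudocount,
                 positive_class = positive_class,
                 decision_threshold = settings$decision_threshold)
}

#' Sweep the significance-threshold multiplier
#'
#' Utility for choosing the empirical multiplier: for each candidate value
#' the first-level feature count on the full table and the cross-validated
#' error (over a small number of repeats) are recorded. Feature-set size
#' decreases monotonically in the multiplier while the error rate typically
#' has a flat minimum around a stable value.
#'
#' @param tbl a [sample_table()].
#' @param multipliers numeric vector of candidate multipliers.
#' @param plan a [cv_plan()] (keep `n_repeats` small here).
#' @param settings a [bn_settings()].
#' @return data.frame with `multiplier`, `n_first_level`, `cv_error_mean`,
#'   `cv_error_sd`.
#' @export
sweep_multiplier <- function(tbl, multipliers = seq(1, 5, by = 0.5),
                             plan = cv_plan(n_repeats = 5L),
                             settings = bn_settings()) {
  base <- permutation_baseline(tbl, n_perm = settings$n_perm, multiplier = 1,
                               seed = settings$seed,
                               exhaustive_cap = settings$exhaustive_cap,
                               n_candidates = settings$n_candidates)
  disc <- discretize_table(tbl, exhaustive_cap = settings$exhaustive_cap,
                           n_candidates = settings$n_candidates)
  out <- lapply(multipliers, function(m) {
    thr <- threshold_spec(base$baseline_mi, multiplier = m,
                          n_perm = base$n_perm, seed = base$seed)
    fl <- suppressWarnings(select_first_level(disc, thr))
    rep <- run_cv(tbl, plan, settings, thr = thr)
    es <- error_summary(rep)
    data.frame(multiplier = m, n_first_level = length(fl),
               cv_error_mean = es$mean, cv_error_sd = es$sd)
  })
  do.call(rbind, out)
}
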