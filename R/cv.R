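# Repeated stratified k-fold cross-validation.
#
# Each repeat re-randomizes the fold assignment; within each fold the
# discretization, feature selection and network construction are done on
# the training cases only, the held-out fold is binned with the frozen
# training boundaries and classified, and the resulting network's arcs are
# tallied. n repeats of k folds yield n*k networks and n cross-validated
# error rates; arc frequencies over those networks measure the stability
# of the selected feature set.

#' Cross-validation plan
#'
#' @param k number of folds (default 10).
#' @param n_repeats number of repeats (default 100).
#' @param stratified keep each fold's class proportions within one case of
#'   the population proportions (default `TRUE`).
#' @param seed integer seed; repeat `r` draws its fold assignment from the
#'   derived substream `seed + r`, so any single repeat can be reproduced
#'   in isolation.
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(k = 10L, n_repeats = 100L, stratified = TRUE, seed = 1L) {
  stopifnot(k >= 2L, n_repeats >= 1L)
  structure(list(k = as.integer(k), n_repeats = as.integer(n_repeats),
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_plan")
}

# fold assignment for one repeat: returns integer fold id per case.
# Stratified dealing: shuffle units within each class, deal round-robin.
# When the table has case groups, whole groups are dealt so replicates of
# one patient share a fold.
assign_folds <- function(tbl, k, stratified) {
  n <- nrow(tbl$abundances)
  fold <- integer(n)
  if (!is.null(tbl$groups)) {
    units <- unique(tbl$groups)
    unit_class <- tbl$class_labels[match(units, tbl$groups)]
    strata <- if (stratified) split(units, unit_class) else list(units)
    for (s in strata) {
      s <- s[sample.int(length(s))]
      uf <- rep_len(seq_len(k), length(s))
      for (i in seq_along(s)) fold[tbl$groups == s[i]] <- uf[i]
    }
  } else {
    strata <- if (stratified) split(seq_len(n), tbl$class_labels) else
      list(seq_len(n))
    for (s in strata) {
      s <- s[sample.int(length(s))]
      fold[s] <- rep_len(seq_len(k), length(s))
    }
  }
  fold
}

#' Run repeated stratified k-fold cross-validation
#'
#' Per fold: the training cases are discretized (boundaries never see the
#' test fold), first-level features are selected against the significance
#' threshold, the network is built by [link_features()] and
#' [orient_and_prune()], classifier parameters are fitted, and the held-out
#' fold is binned with the frozen training boundaries and classified. The
#' permutation baseline is computed once on the full table before
#' cross-validation (set `recompute_threshold` in [bn_settings()] to
#' recompute it per fold instead).
#'
#' @param tbl a [sample_table()].
#' @param plan a [cv_plan()].
#' @param settings a [bn_settings()].
#' @param thr optional precomputed [threshold_spec()] (skips the
#'   permutation baseline).
#' @param keep_fold_details record per-fold boundaries, first-level sets
#'   and arcs (memory-heavy; default `FALSE`).
#' @return object of class `stability_report`: `arc_counts` (data.frame
#'   `from`, `to`, `level`, `count`), `n_networks`, `repeat_error_rates`,
#'   `threshold`, `settings`, `plan`, and optionally `fold_details`.
#' @export
run_cv <- function(tbl, plan = cv_plan(), settings = bn_settings(),
                   thr = NULL, keep_fold_details = FALSE) {
  stopifnot(inherits(tbl, "sample_table"), inherits(plan, "cv_plan"))
  n <- nrow(tbl$abundances)
  class_counts <- table(tbl$class_labels)
  if (plan$stratified && plan$k > min(class_counts)) {
    stop("k (", plan$k, ") exceeds the smallest class count (",
         min(class_counts), ")")
  }
  if (plan$k > n) stop("k (", plan$k, ") exceeds the number of cases")
  if (is.null(thr) && !settings$recompute_threshold) {
    thr <- permutation_baseline(tbl, n_perm = settings$n_perm,
                                multiplier = settings$multiplier,
                                seed = settings$seed,
                                exhaustive_cap = settings$exhaustive_cap,
                                n_candidates = settings$n_candidates)
  }
  tally <- new.env(parent = emptyenv())
  errors <- numeric(plan$n_repeats)
  details <- if (keep_fold_details) vector("list", plan$n_repeats) else NULL

  for (r in seq_len(plan$n_repeats)) {
    fold <- with_local_seed(plan$seed + r,
                            assign_folds(tbl, plan$k, plan$stratified))
    miscls <- 0L
    rdet <- if (keep_fold_details) vector("list", plan$k) else NULL
    for (f in seq_len(plan$k)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      train <- subset_cases(tbl, train_idx)
      disc <- discretize_table(train,
                               exhaustive_cap = settings$exhaustive_cap,
                               n_candidates = settings$n_candidates)
      thr_f <- if (settings$recompute_threshold) {
        permutation_baseline(train, n_perm = settings$n_perm,
                             multiplier = settings$multiplier,
                             seed = settings$seed + r * plan$k + f,
                             exhaustive_cap = settings$exhaustive_cap,
                             n_candidates = settings$n_candidates,
                             disc = disc)
      } else thr
      fl <- suppressWarnings(select_first_level(disc, thr_f))
      net <- NULL
      if (length(fl) > 0L) {
        links <- link_features(disc, fl, thr_f)
        op <- orient_and_prune(disc, fl, links,
                               drop_threshold = settings$drop_threshold,
                               multi_parent = settings$multi_parent)
        net <- op$net
        for (i in seq_len(nrow(net$arcs))) {
          key <- paste(net$arcs$from[i], net$arcs$to[i], net$arcs$level[i],
                       sep = "\r")
          tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
        }
        params <- fit_parameters(net, disc,
                                 pseudocount = settings$pseudocount,
                                 decision_threshold = settings$decision_threshold)
        res <- classify(params, subset_cases(tbl, test_idx))
        miscls <- miscls + sum(res$calls != tbl$class_labels[test_idx])
      } else {
        # no selected feature: predict the training majority class
        maj <- names(which.max(table(train$class_labels)))
        miscls <- miscls + sum(tbl$class_labels[test_idx] != maj)
      }
      if (keep_fold_details) {
        rdet[[f]] <- list(test_idx = test_idx, b_low = disc$b_low,
                          b_high = disc$b_high, first_level = fl,
                          arcs = if (is.null(net)) NULL else net$arcs)
      }
    }
    errors[r] <- miscls / n
    if (keep_fold_details) details[[r]] <- rdet
  }

  keys <- ls(tally)
  if (length(keys) > 0L) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    arc_counts <- data.frame(from = parts[, 1L], to = parts[, 2L],
                             level = parts[, 3L],
                             count = vapply(keys, function(k) tally[[k]], 0L),
                             row.names = NULL, stringsAsFactors = FALSE)
    arc_counts <- arc_counts[order(-arc_counts$count, arc_counts$from,
                                   arc_counts$to), , drop = FALSE]
    rownames(arc_counts) <- NULL
  } else {
    arc_counts <- data.frame(from = character(0), to = character(0),
                             level = character(0), count = integer(0))
  }
  structure(list(arc_counts = arc_counts,
                 n_networks = plan$n_repeats * plan$k,
                 repeat_error_rates = errors,
                 threshold = if (settings$recompute_threshold) NULL else thr,
                 settings = settings, plan = plan,
                 fold_details = details),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  es <- error_summary(x)
  cat("Stability report: ", x$n_networks, " networks (",
      x$plan$n_repeats, " repeats x ", x$plan$k, "-fold CV)\n", sep = "")
  cat(sprintf("  CV error: %.1f%% +/- %.1f%%\n", 100 * es$mean, 100 * es$sd))
  cl <- x$arc_counts[x$arc_counts$from == CLASS_NODE, , drop = FALSE]
  top <- utils::head(cl, 8L)
  if (nrow(top) > 0L) {
    cat("  top class arcs: ",
        paste(sprintf("%s (%.0f%%)", top$to, 100 * top$count / x$n_networks),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Mean and SD of the per-repeat cross-validated error rates
#'
#' @param report a [run_cv()] stability report.
#' @return list with `mean` and `sd` (sample standard deviation; `NA` with
#'   a single repeat).
#' @export
error_summary <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  e <- report$repeat_error_rates
  if (length(e) == 0L) stop("empty report")
  list(mean = mean(e), sd = stats::sd(e))
}

#' Arc selection frequencies
#'
#' @param report a [run_cv()] stability report.
#' @param class_only restrict to class->feature arcs (default `TRUE`).
#' @return data.frame `from`, `to`, `level`, `count`, `frequency` sorted by
#'   decreasing frequency.
#' @export
arc_frequencies <- function(report, class_only = TRUE) {
  stopifnot(inherits(report, "stability_report"))
  ac <- report$arc_counts
  if (class_only) ac <- ac[ac$from == CLASS_NODE, , drop = FALSE]
  ac$frequency <- ac$count / report$n_networks
  ac
}

#' Write a stability report to JSON
#'
#' The JSON body records the full settings, the arc tallies and the
#' per-repeat error rates (no timestamps), so identical runs produce
#' byte-identical reports.
#'
#' @param report a [run_cv()] stability report.
#' @param path output path.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  obj <- list(settings = unclass(report$settings),
              plan = unclass(report$plan),
              threshold = if (is.null(report$threshold)) NULL else
                unclass(report$threshold)[c("baseline_mi", "multiplier",
                                            "effective_threshold", "n_perm",
                                            "seed")],
              n_networks = report$n_networks,
              repeat_error_rates = report$repeat_error_rates,
              arc_counts = report$arc_counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stability report from JSON
#'
#' @param path file written by [write_stability_report()].
#' @return a `stability_report`.
#' @export
read_stability_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- NULL
  if (!is.null(obj$threshold)) {
    thr <- threshold_spec(obj$threshold$baseline_mi, obj$threshold$multiplier,
                          n_perm = obj$threshold$n_perm,
                          seed = obj$threshold$seed)
  }
  structure(list(arc_counts = as.data.frame(obj$arc_counts),
                 n_networks = obj$n_networks,
                 repeat_error_rates = obj$repeat_error_rates,
                 threshold = thr,
                 settings = do.call(bn_settings, obj$settings[
                   setdiff(names(obj$settings), character(0))]),
                 plan = do.call(cv_plan, obj$plan),
                 fold_details = NULL),
            class = "stability_report")
}

#' Arc-frequency bar chart
#'
#' Renders the class-arc selection frequencies across all recorded
#' networks (the stability profile of the feature selection).
#'
#' @param report a [run_cv()] stability report.
#' @param top_n number of features shown (default 20).
#' @return a ggplot object.
#' @export
plot_arc_frequencies <- function(report, top_n = 20L) {
  af <- arc_frequencies(report)
  af <- utils::head(af, top_n)
  af$feature <- factor(af$to, levels = af$to)
  ggplot2::ggplot(af, ggplot2::aes(x = .data$feature,
                                   y = 100 * .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "feature (m/z)",
                  y = "class-arc selection frequency (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
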