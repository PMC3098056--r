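# Markov-blanket classifier on a fixed class-rooted network.
#
# Only first-level features enter the classifier: they form the Markov
# blanket of the class node, so child features add no further information.
# P(class | bins) is proportional to P(class) * prod_f P(bin_f | class)
# with Laplace-smoothed conditional probability tables, accumulated in log
# space.

#' Fit classifier parameters for a network
#'
#' Estimates the class prior and, for every first-level feature, a
#' 3 x #classes conditional probability table P(bin | class) by smoothed
#' empirical counts. The discretization boundaries of the training data are
#' frozen into the parameters so new data can be binned identically.
#'
#' @param net a [bn_net()] with at least one first-level feature.
#' @param disc the training [discretize_table()] result (its boundaries are
#'   frozen into the classifier).
#' @param pseudocount Laplace smoothing count added to every bin
#'   (default 1); with a positive pseudocount every CPT entry is strictly
#'   positive.
#' @param positive_class label treated as "positive" for posteriors, calls
#'   and ROC curves; defaults to the second class level in first-seen
#'   order.
#' @param decision_threshold posterior strictly above which the positive
#'   class is called (default 0.5; a posterior exactly at the threshold is
#'   a negative call).
#' @return object of class `bn_classifier`: `class_levels`, `prior`,
#'   `cpts` (named list of 3 x #classes matrices), `b_low`, `b_high`,
#'   `features`, `positive_class`, `decision_threshold`, `pseudocount`.
#' @export
fit_parameters <- function(net, disc, pseudocount = 1,
                           positive_class = NULL, decision_threshold = 0.5) {
  stopifnot(inherits(net, "bn_net"), inherits(disc, "disc_table"))
  feats <- first_level_features(net)
  if (length(feats) == 0L) stop("network has no first-level feature")
  missing <- setdiff(feats, colnames(disc$bins))
  if (length(missing) > 0L) {
    stop("features absent from the discretized table: ",
         paste(missing, collapse = ", "))
  }
  labels <- disc$class_labels
  levels <- disc$class_levels
  if (length(levels) < 2L) stop("training data must contain at least 2 classes")
  nc <- vapply(levels, function(l) sum(labels == l), 0L)
  if (any(nc == 0L)) {
    stop("class absent from training data: ", levels[nc == 0L][1L])
  }
  prior <- nc / sum(nc)
  names(prior) <- levels
  cpts <- lapply(feats, function(f) {
    b <- disc$bins[, f]
    cpt <- vapply(levels, function(l) {
      cnt <- tabulate(b[labels == l] + 1L, nbins = 3L)
      (cnt + pseudocount) / (sum(cnt) + 3 * pseudocount)
    }, numeric(3))
    rownames(cpt) <- c("low", "medium", "high")
    cpt
  })
  names(cpts) <- feats
  if (is.null(positive_class)) positive_class <- levels[2L]
  if (!positive_class %in% levels) {
    stop("positive class '", positive_class, "' not among class levels")
  }
  structure(list(class_levels = levels, prior = prior, cpts = cpts,
                 b_low = disc$b_low[feats], b_high = disc$b_high[feats],
                 features = feats, positive_class = positive_class,
                 decision_threshold = decision_threshold,
                 pseudocount = pseudocount),
            class = "bn_classifier")
}

#' @export
print.bn_classifier <- function(x, ...) {
  cat("Markov-blanket classifier: ", length(x$features), " features [",
      paste(x$features, collapse = ", "), "]\n", sep = "")
  cat("  classes: ", paste(x$class_levels, collapse = " / "),
      " (positive: ", x$positive_class, ")\n", sep = "")
  cat("  decision threshold: ", x$decision_threshold, "\n", sep = "")
  invisible(x)
}

#' Posterior class probabilities for discretized cases
#'
#' Accumulates log prior plus per-feature log conditional probabilities and
#' normalizes with the log-sum-exp trick, so thousands of features cannot
#' underflow.
#'
#' @param params a [fit_parameters()] classifier.
#' @param bins integer matrix (cases x features, values in 0:2) whose
#'   columns cover `params$features`, or a single case as a named vector.
#' @return matrix (cases x classes) of posterior probabilities; each row
#'   sums to 1.
#' @export
posterior <- function(params, bins) {
  stopifnot(inherits(params, "bn_classifier"))
  if (!is.matrix(bins)) bins <- matrix(bins, nrow = 1L,
                                       dimnames = list(NULL, names(bins)))
  missing <- setdiff(params$features, colnames(bins))
  if (length(missing) > 0L) {
    stop("case is missing classifier feature(s): ",
         paste(missing, collapse = ", "))
  }
  sub <- bins[, params$features, drop = FALSE]
  if (any(!(sub %in% 0:2))) stop("bin values must be in {0, 1, 2}")
  n <- nrow(sub)
  k <- length(params$class_levels)
  logp <- matrix(rep(log(params$prior), each = n), n, k)
  for (f in params$features) {
    cpt <- params$cpts[[f]]
    logp <- logp + log(cpt[sub[, f] + 1L, , drop = FALSE])
  }
  mx <- apply(logp, 1L, max)
  p <- exp(logp - mx)
  p <- p / rowSums(p)
  colnames(p) <- params$class_levels
  p
}

#' Classify cases with a frozen classifier
#'
#' Applies the frozen training boundaries to the raw abundances, computes
#' posteriors, and converts them to deterministic calls: for the binary
#' problem the positive class is called when its posterior strictly exceeds
#' the decision threshold (ties go to the negative class); with more than
#' two classes the maximum-posterior class is called.
#'
#' @param params a [fit_parameters()] classifier.
#' @param tbl a [sample_table()] (its labels, if present, are used for the
#'   error rate and ROC), or a bare numeric matrix with m/z column names.
#' @param labels optional labels overriding the table's own.
#' @return list with `calls`, `posterior` (cases x classes), `error_rate`
#'   (fraction misclassified, `NA` without labels), and `roc` (data.frame
#'   of `threshold`, `fpr`, `tpr`, `NA` without labels).
#' @export
classify <- function(params, tbl, labels = NULL) {
  stopifnot(inherits(params, "bn_classifier"))
  if (inherits(tbl, "sample_table")) {
    x <- tbl$abundances
    if (is.null(labels)) labels <- tbl$class_labels
  } else {
    x <- as.matrix(tbl)
  }
  missing <- setdiff(params$features, colnames(x))
  if (length(missing) > 0L) {
    stop("table is missing classifier feature(s): ",
         paste(missing, collapse = ", "))
  }
  sub <- x[, params$features, drop = FALSE]
  bins <- apply_boundaries(sub, params$b_low, params$b_high)
  post <- posterior(params, bins)
  pos <- params$positive_class
  levels <- params$class_levels
  if (length(levels) == 2L) {
    neg <- setdiff(levels, pos)
    calls <- ifelse(post[, pos] > params$decision_threshold, pos, neg)
  } else {
    calls <- levels[max.col(post, ties.method = "first")]
  }
  error_rate <- NA_real_
  roc <- NULL
  if (!is.null(labels)) {
    if (length(labels) != nrow(post)) stop("labels length mismatch")
    error_rate <- mean(calls != labels)
    roc <- roc_points(post[, pos], labels == pos)
  }
  list(calls = calls, posterior = post, error_rate = error_rate, roc = roc)
}

#' ROC points from positive-class scores
#'
#' Sweeps the decision threshold over `[0, 1]` (all distinct score values
#' plus the endpoints); at each threshold a case is called positive when
#' its score strictly exceeds the threshold.
#'
#' @param scores posterior probability of the positive class.
#' @param truth logical vector (TRUE = positive).
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered by
#'   decreasing threshold so `fpr` and `tpr` are non-decreasing.
#' @export
roc_points <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  thr <- sort(unique(c(0, 1, scores)), decreasing = TRUE)
  npos <- sum(truth)
  nneg <- sum(!truth)
  tpr <- vapply(thr, function(t) sum(scores > t & truth) / max(npos, 1L), 0)
  fpr <- vapply(thr, function(t) sum(scores > t & !truth) / max(nneg, 1L), 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Serialize a frozen classifier to JSON
#'
#' Stores class levels, prior, CPTs, frozen boundaries and decision
#' settings so a classifier can be shipped and applied later without
#' refitting.
#'
#' @param params a [fit_parameters()] classifier.
#' @param path output path.
#' @export
write_classifier <- function(params, path) {
  stopifnot(inherits(params, "bn_classifier"))
  obj <- list(class_levels = params$class_levels,
              prior = as.list(params$prior),
              features = params$features,
              cpts = lapply(params$cpts, function(m) {
                stats::setNames(lapply(seq_len(ncol(m)), function(j) m[, j]),
                                colnames(m))
              }),
              b_low = as.list(params$b_low),
              b_high = as.list(params$b_high),
              positive_class = params$positive_class,
              decision_threshold = params$decision_threshold,
              pseudocount = params$pseudocount)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a frozen classifier from JSON
#'
#' @param path file written by [write_classifier()].
#' @return a `bn_classifier`.
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- obj$features
  cpts <- lapply(feats, function(f) {
    m <- vapply(obj$class_levels, function(l) unlist(obj$cpts[[f]][[l]]),
                numeric(3))
    rownames(m) <- c("low", "medium", "high")
    m
  })
  names(cpts) <- feats
  structure(list(class_levels = obj$class_levels,
                 prior = unlist(obj$prior)[obj$class_levels],
                 cpts = cpts,
                 b_low = unlist(obj$b_low)[feats],
                 b_high = unlist(obj$b_high)[feats],
                 features = feats,
                 positive_class = obj$positive_class,
                 decision_threshold = obj$decision_threshold,
                 pseudocount = obj$pseudocount),
            class = "bn_classifier")
}
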