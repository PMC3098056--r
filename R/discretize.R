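# Three-bin discretization by mutual-information maximization.
#
# Each continuous peak abundance is cut into low / medium / high levels by a
# boundary pair chosen to maximize MI(class; binned feature). Central,
# non-discriminative values end up in the middle bin; for a diagnostic
# feature the low and high bins capture most of the class contrast.

#' Discretize one feature by maximizing mutual information with the class
#'
#' Sweeps a candidate grid of boundary pairs `(b_low, b_high)` over the
#' empirical range of `values` and returns the pair maximizing
#' `MI(class_labels; binned values)`. The binning convention is:
#' bin 0 (low) iff `value < b_low`, bin 2 (high) iff `value > b_high`,
#' otherwise bin 1 (medium); a value exactly on a boundary falls in the
#' middle bin.
#'
#' When the number of distinct values is at most `exhaustive_cap` the grid
#' is the midpoints between consecutive sorted distinct values and every
#' pair `b_low < b_high` is evaluated (the exhaustive reference mode).
#' Otherwise the grid is the midpoints of `n_candidates + 1` evenly spaced
#' sample quantiles.
#'
#' Degenerate inputs fall back gracefully: with two distinct values a
#' single boundary at their midpoint yields a two-level binning
#' (`degenerate = "two-level"`); a constant feature is assigned the middle
#' bin everywhere with `mi = 0` (`degenerate = "constant"`).
#'
#' @param values numeric vector of abundances.
#' @param class_labels discrete vector of the same length.
#' @param exhaustive_cap maximum distinct-value count for the exhaustive
#'   grid (default 64).
#' @param n_candidates number of quantile-derived candidate boundaries used
#'   above the cap (default 64).
#' @return list with `b_low`, `b_high`, `bins` (integer vector in 0:2),
#'   `mi` (bits), and `degenerate` (`"none"`, `"two-level"` or
#'   `"constant"`).
#' @export
discretize_max_mi <- function(values, class_labels,
                              exhaustive_cap = 64L, n_candidates = 64L) {
  n <- length(values)
  if (length(class_labels) != n) {
    stop("`values` and `class_labels` must have the same length")
  }
  if (n == 0L) stop("empty input")
  if (anyNA(values)) stop("`values` contains missing values")
  cl <- as_codes(class_labels)
  nclass <- length(cl$levels)
  u <- sort(unique(values))
  d <- length(u)

  if (d == 1L) {
    return(list(b_low = u, b_high = u, bins = rep(1L, n), mi = 0,
                degenerate = "constant"))
  }
  if (d == 2L) {
    b <- (u[1L] + u[2L]) / 2
    bins <- ifelse(values > b, 2L, 0L)
    mi <- fast_mi(cl$codes, bins %/% 2L, nclass, 2L)
    return(list(b_low = b, b_high = b, bins = as.integer(bins), mi = mi,
                degenerate = "two-level"))
  }

  by_class <- lapply(seq_len(nclass) - 1L,
                     function(c) sort(values[cl$codes == c]))
  tot <- lengths(by_class)

  if (d <= exhaustive_cap) {
    cand <- (u[-d] + u[-1L]) / 2
    best <- best_boundary_pair(cand, by_class, tot, n)
  } else {
    qs <- stats::quantile(values,
                          probs = seq(0, 1, length.out = n_candidates + 1L),
                          names = FALSE, type = 7)
    cand <- sort(unique((qs[-length(qs)] + qs[-1L]) / 2))
    cand <- cand[cand > u[1L] & cand < u[d]]
    if (length(cand) < 2L) cand <- (u[-d] + u[-1L]) / 2
    best <- best_boundary_pair(cand, by_class, tot, n)
    # local refinement: exhaustive search over the distinct-value midpoints
    # within one coarse-grid step of the coarse optimum
    mids <- (u[-d] + u[-1L]) / 2
    step <- diff(range(cand)) / (length(cand) - 1L)
    lo_set <- mids[mids >= best$b_low - step & mids <= best$b_low + step]
    hi_set <- mids[mids >= best$b_high - step & mids <= best$b_high + step]
    if (length(lo_set) > 0L && length(hi_set) > 0L) {
      ref <- best_boundary_pair(sort(unique(c(lo_set, best$b_low))),
                                by_class, tot, n,
                                cand_high = sort(unique(c(hi_set, best$b_high))))
      if (ref$mi > best$mi) best <- ref
    }
  }
  b_low <- best$b_low
  b_high <- best$b_high
  bins <- apply_boundaries(values, b_low, b_high)
  # recompute through the public MI path so the reported value is exact
  mi <- fast_mi(cl$codes, bins, nclass, 3L)
  list(b_low = b_low, b_high = b_high, bins = bins, mi = mi,
       degenerate = "none")
}

# Evaluate MI(class; 3-binned values) for every boundary pair on a grid and
# return the best. `cand_high` defaults to `cand_low` (all pairs i < j of
# one grid); when given, the full low x high cross product with
# b_low < b_high is searched. Counts come from per-class prefix sums, so
# the cost is O(#pairs * #classes) after an O(n log n) sort. Ties resolve
# to the first pair in column-major order (deterministic).
best_boundary_pair <- function(cand_low, by_class, tot, n, cand_high = NULL) {
  same_grid <- is.null(cand_high)
  if (same_grid) cand_high <- cand_low
  nclass <- length(by_class)
  cntL <- vapply(seq_len(nclass), function(c) {
    findInterval(cand_low, by_class[[c]], left.open = TRUE) # strict <
  }, numeric(length(cand_low)))
  cntG <- vapply(seq_len(nclass), function(c) {
    tot[c] - findInterval(cand_high, by_class[[c]])         # strict >
  }, numeric(length(cand_high)))
  cntL <- matrix(cntL, ncol = nclass)
  cntG <- matrix(cntG, ncol = nclass)
  if (same_grid) {
    m <- length(cand_low)
    pr <- which(upper.tri(matrix(NA, m, m)), arr.ind = TRUE)
    ii <- pr[, 1L]; jj <- pr[, 2L]
  } else {
    grid <- expand.grid(i = seq_along(cand_low), j = seq_along(cand_high))
    keep <- cand_low[grid$i] < cand_high[grid$j]
    ii <- grid$i[keep]; jj <- grid$j[keep]
  }
  np <- length(ii)
  if (np == 0L) return(list(b_low = NA_real_, b_high = NA_real_, mi = -Inf))
  mi_all <- numeric(np)
  lowT <- numeric(np); midT <- numeric(np); highT <- numeric(np)
  L <- matrix(0, np, nclass); M <- matrix(0, np, nclass); H <- matrix(0, np, nclass)
  for (c in seq_len(nclass)) {
    L[, c] <- cntL[ii, c]
    H[, c] <- cntG[jj, c]
    M[, c] <- tot[c] - L[, c] - H[, c]
  }
  lowT <- rowSums(L); midT <- rowSums(M); highT <- rowSums(H)
  mi_term <- function(cnt, bin_tot, cls_tot) {
    out <- numeric(np)
    nz <- cnt > 0
    out[nz] <- cnt[nz] / n * log2(cnt[nz] * n / (bin_tot[nz] * cls_tot))
    out
  }
  for (c in seq_len(nclass)) {
    mi_all <- mi_all + mi_term(L[, c], lowT, tot[c]) +
      mi_term(M[, c], midT, tot[c]) + mi_term(H[, c], highT, tot[c])
  }
  best <- which.max(mi_all)
  list(b_low = cand_low[ii[best]], b_high = cand_high[jj[best]],
       mi = mi_all[best])
}

#' Apply frozen bin boundaries to new values
#'
#' @param values numeric vector or matrix.
#' @param b_low,b_high boundaries (scalars for a vector, per-column vectors
#'   for a matrix). Values below `b_low` map to 0, above `b_high` to 2,
#'   all others (including exact boundary hits) to 1. Out-of-range values
#'   in new data are binned like any other value.
#' @return integer vector or matrix of bins in `{0, 1, 2}`.
#' @export
apply_boundaries <- function(values, b_low, b_high) {
  if (is.matrix(values)) {
    lo <- matrix(b_low, nrow(values), ncol(values), byrow = TRUE)
    hi <- matrix(b_high, nrow(values), ncol(values), byrow = TRUE)
    out <- (values > hi) - (values < lo) + 1L
    storage.mode(out) <- "integer"
    dimnames(out) <- dimnames(values)
    return(out)
  }
  as.integer((values > b_high) - (values < b_low) + 1L)
}

#' Discretize every feature of a sample table
#'
#' Runs [discretize_max_mi()] per feature against the class labels and
#' collects the binned matrix, the boundary pairs, and the per-feature
#' maximized MI values.
#'
#' @param tbl a [sample_table()].
#' @param class_labels labels to discretize against; defaults to the
#'   table's own labels (cross-validation passes training labels here).
#' @param exhaustive_cap,n_candidates see [discretize_max_mi()].
#' @return an object of class `disc_table`: list with `bins` (integer
#'   matrix, cases x features), `b_low`, `b_high`, `per_feature_mi`,
#'   `degenerate` (per-feature flags), `feature_ids`, `class_labels` and
#'   `class_levels`.
#' @export
discretize_table <- function(tbl, class_labels = tbl$class_labels,
                             exhaustive_cap = 64L, n_candidates = 64L) {
  stopifnot(inherits(tbl, "sample_table"))
  x <- tbl$abundances
  p <- ncol(x)
  bins <- matrix(0L, nrow(x), p, dimnames = dimnames(x))
  b_low <- numeric(p)
  b_high <- numeric(p)
  mi <- numeric(p)
  degen <- character(p)
  for (j in seq_len(p)) {
    dj <- discretize_max_mi(x[, j], class_labels,
                            exhaustive_cap = exhaustive_cap,
                            n_candidates = n_candidates)
    bins[, j] <- dj$bins
    b_low[j] <- dj$b_low
    b_high[j] <- dj$b_high
    mi[j] <- dj$mi
    degen[j] <- dj$degenerate
  }
  nm <- colnames(x)
  names(b_low) <- names(b_high) <- names(mi) <- names(degen) <- nm
  structure(list(bins = bins, b_low = b_low, b_high = b_high,
                 per_feature_mi = mi, degenerate = degen,
                 feature_ids = tbl$feature_ids,
                 class_labels = class_labels,
                 class_levels = unique(class_labels)),
            class = "disc_table")
}

#' @export
print.disc_table <- function(x, ...) {
  cat("Discretized peak table: ", nrow(x$bins), " cases x ", ncol(x$bins),
      " features\n", sep = "")
  cat("  per-feature MI(class; bins): ",
      sprintf("%.4f", min(x$per_feature_mi)), " - ",
      sprintf("%.4f", max(x$per_feature_mi)), " bits\n", sep = "")
  ndeg <- sum(x$degenerate != "none")
  if (ndeg > 0) cat("  degenerate features:", ndeg, "\n")
  invisible(x)
}
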