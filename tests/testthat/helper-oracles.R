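# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use table() and explicit double loops, sharing no code
# with the package internals.

brute_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  as.numeric(mi)
}

brute_cmi <- function(c, v2, v1) {
  n <- length(c)
  out <- 0
  for (s in unique(v1)) {
    idx <- v1 == s
    if (sum(idx) >= 1 && length(unique(c[idx])) >= 1) {
      out <- out + sum(idx) / n * brute_mi(c[idx], v2[idx])
    }
  }
  out
}

# exhaustive search over all midpoint boundary pairs by direct enumeration
brute_discretize <- function(values, labels) {
  u <- sort(unique(values))
  cand <- (u[-length(u)] + u[-1]) / 2
  best <- list(mi = -1)
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (j <= i) next
      bins <- ifelse(values < cand[i], 0L, ifelse(values > cand[j], 2L, 1L))
      mi <- brute_mi(labels, bins)
      if (mi > best$mi + 1e-12) {
        best <- list(b_low = cand[i], b_high = cand[j], mi = mi)
      }
    }
  }
  best
}

# small labelled two-class table with a diagnostic and a noise feature
make_two_feature_table <- function(n_per_class = 100, sep = 2, seed = 1) {
  set.seed(seed)
  lab <- rep(c("normal", "disease"), each = n_per_class)
  diag <- rnorm(2 * n_per_class, 50, 10) +
    ifelse(lab == "disease", sep * 5, -sep * 5)
  noise <- rnorm(2 * n_per_class, 30, 6)
  sample_table(cbind(`3000` = diag, `5000` = noise), lab)
}
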