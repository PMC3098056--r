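# Mutual information and conditional mutual information on discrete vectors.
# All quantities are in bits (log base 2); probabilities are plain empirical
# frequencies and 0 * log(0) terms are defined as 0.

#' Coerce a discrete vector to 0-based integer codes
#'
#' Levels are taken in first-seen order so that the coding is deterministic
#' for a given input ordering.
#'
#' @param x atomic vector or factor.
#' @return list with `codes` (0-based integer vector) and `levels`.
#' @keywords internal
#' @noRd
as_codes <- function(x) {
  if (is.factor(x)) {
    lev <- levels(x)[unique(as.integer(x))]
    x <- as.character(x)
  } else {
    lev <- unique(x)
  }
  list(codes = match(x, lev) - 1L, levels = lev)
}

# MI in bits from 0-based codes with known alphabet sizes; the hot path used
# throughout network construction (avoids table()).
fast_mi <- function(xi, yi, nx, ny) {
  n <- length(xi)
  joint <- tabulate(xi * ny + yi + 1L, nbins = nx * ny)
  px <- tabulate(xi + 1L, nbins = nx)
  py <- tabulate(yi + 1L, nbins = ny)
  nz <- joint > 0L
  if (!any(nz)) return(0)
  jx <- (seq_len(nx * ny) - 1L) %/% ny + 1L
  jy <- (seq_len(nx * ny) - 1L) %% ny + 1L
  j <- joint[nz]
  sum(j / n * log2(j * n / (px[jx[nz]] * py[jy[nz]])))
}

#' Mutual information between two discrete vectors
#'
#' Computes \eqn{MI(X;Y) = \sum_{x,y} P(x,y) \log_2 \frac{P(x,y)}{P(x)P(y)}}
#' with maximum-likelihood (empirical frequency) probability estimates.
#' The result is in bits, is symmetric in its arguments, and lies in
#' `[0, log2(min(|X|, |Y|))]` where `|X|` is the alphabet size of `x`.
#'
#' @param x,y discrete vectors (factors, integers, or character) of equal
#'   length.
#' @return Mutual information in bits (non-negative scalar).
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(1, 1, 0, 0)) # 1 bit
#' mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)) # 0 bits
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length (", length(x), " vs ",
         length(y), ")")
  }
  if (length(x) == 0L) stop("empty input")
  cx <- as_codes(x)
  cy <- as_codes(y)
  fast_mi(cx$codes, cy$codes, length(cx$levels), length(cy$levels))
}

#' Conditional mutual information MI(c; v2 | v1)
#'
#' The data are partitioned by the value of the conditioning variable `v1`,
#' mutual information between `c` and `v2` is computed within each stratum,
#' and the stratum values are combined weighted by the stratum probabilities:
#' \eqn{\sum_{v_1} P(v_1)\, MI(c; v_2 \mid v_1)}.
#'
#' For a serial chain class -> v1 -> v2 the conditional mutual information
#' `conditional_mutual_information(c, v2, v1)` vanishes: once the parent is
#' known the child carries no further information about the class.
#'
#' @param c class (or any discrete) vector.
#' @param v2 discrete vector whose remaining information about `c` is
#'   measured.
#' @param v1 conditioning discrete vector.
#' @return Conditional mutual information in bits (non-negative scalar).
#' @export
conditional_mutual_information <- function(c, v2, v1) {
  n <- length(c)
  if (length(v2) != n || length(v1) != n) {
    stop("`c`, `v2` and `v1` must have the same length")
  }
  if (n == 0L) stop("empty input")
  cc <- as_codes(c)
  c2 <- as_codes(v2)
  c1 <- as_codes(v1)
  out <- 0
  for (s in seq_along(c1$levels) - 1L) {
    idx <- c1$codes == s
    ns <- sum(idx)
    if (ns < 1L) next
    # re-code within the stratum so alphabet sizes stay tight
    xi <- cc$codes[idx]
    yi <- c2$codes[idx]
    out <- out + ns / n *
      fast_mi(xi, yi, length(cc$levels), length(c2$levels))
  }
  out
}
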