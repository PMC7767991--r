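#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact inference on the table
#' \preformatted{
#'              lesion+   lesion-
#'  recurrence     a         b
#'  psp            c         d
#' }
#' with all margins fixed. Under the null, the first cell k follows the
#' hypergeometric law with point probability
#' \deqn{P(k) = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{k!\,(a+b-k)!\,(a+c-k)!\,(d-a+k)!\,n!}.}
#' The two-tailed p-value is the "method of small P": the sum of P(k) over
#' every feasible k whose point probability does not exceed the observed one,
#' with a relative slack of 1e-7 to absorb log-space rounding. Computed in
#' log space via `lgamma`, so it is stable for any cohort size.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The two-tailed exact p-value in (0, 1].
#' @examples
#' fisher_two_tailed(5, 5, 5, 5)    # modal table -> 1
#' fisher_two_tailed(10, 0, 0, 10)  # 2 / choose(20, 10)
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  # log point probability of each feasible table, margins fixed
  lconst <- lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) +
    lgamma(c2 + 1) - lgamma(n + 1)
  lp <- lconst - lgamma(k + 1) - lgamma(r1 - k + 1) - lgamma(c1 - k + 1) -
    lgamma(r2 - c1 + k + 1)
  lp_obs <- lp[k == a]
  keep <- lp <= lp_obs + log1p(1e-7)
  p <- sum(exp(lp[keep]))
  min(p, 1)
}

#' Memoized p-value table over all achievable voxel contingencies
#'
#' With group sizes fixed across the volume, every voxel's table is determined
#' by (a, c) alone, so the whole map needs at most
#' `(n_rec + 1) * (n_psp + 1)` distinct tests. This table makes voxel-wise
#' testing and permutation re-testing O(1) per voxel.
#'
#' @param n_rec,n_psp Group sizes (row margins).
#' @return Numeric matrix `p[a + 1, c + 1]`.
#' @export
fisher_p_table <- function(n_rec, n_psp) {
  stopifnot(n_rec >= 1, n_psp >= 1)
  p <- matrix(NA_real_, n_rec + 1L, n_psp + 1L)
  for (a in 0:n_rec) {
    for (c in 0:n_psp) {
      p[a + 1L, c + 1L] <- fisher_two_tailed(a, n_rec - a, c, n_psp - c)
    }
  }
  p
}
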