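#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value computed by enumerating the hypergeometric
#' distribution over the support of the table with fixed margins and summing
#' the probabilities of all tables at most as probable as the observed one
#' (with the conventional (1 + 1e-7) relative guard against floating-point
#' ties). Log-space binomial coefficients keep the enumeration exact to
#' machine precision for the sample sizes this package works at (n <= a few
#' hundred individuals).
#'
#' @param tab a 2x2 matrix of non-negative integer counts, or a length-4
#'   vector in row-major order (a, b, c, d).
#' @return the two-sided p-value (a single number in \[0, 1\]).
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, 2))  # 2/choose(20,10)
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  } else {
    if (length(tab) != 4L) stop("tab must be a 2x2 matrix or length-4 vector")
    a <- tab[1]; b <- tab[2]; c_ <- tab[3]; d <- tab[4]
  }
  cnt <- c(a, b, c_, d)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("counts must be non-negative integers")
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- a + b + c_ + d
  if (n == 0L) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  p_obs <- logp[k == a]
  p <- sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
  min(p, 1)
}
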