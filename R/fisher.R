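#' Vectorized two-sided Fisher's exact test for 2x2 tables
#'
#' Computes the two-sided Fisher's exact p-value for tables
#' \code{[[a, b], [c, d]]} by hypergeometric enumeration: the p-value is the
#' sum of probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table. As in
#' \code{stats::fisher.test}, near-ties are absorbed with a relative
#' tolerance of 1e-7 so that tables mathematically as extreme as the observed
#' one are counted despite floating-point rounding. A table with a zero row
#' or column margin carries no information and returns p = 1.
#'
#' A vectorized implementation is used because the locus and DMR callers test
#' thousands of windows; agreement with \code{stats::fisher.test} is part of
#' the test suite.
#'
#' @param a,b,c,d Non-negative integer vectors: first row (a, b), second row
#'   (c, d).
#' @return Numeric vector of two-sided p-values in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) abort("table entries must be non-negative")
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]
    k1 <- a[i] + c[i]; k2 <- b[i] + d[i]
    if (r1 == 0 || r2 == 0 || k1 == 0 || k2 == 0) return(1)
    lo <- max(0, r1 - k2)
    hi <- min(r1, k1)
    supp <- lo:hi
    dens <- stats::dhyper(supp, k1, k2, r1)
    p_obs <- dens[supp == a[i]]
    min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}
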