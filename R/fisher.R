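#' Exact test for a 2x2 carrier table
#'
#' Computes the cross-product odds ratio and an exact conditional
#' (hypergeometric) p-value for a fourfold table
#' \preformatted{              carrier  non-carrier
#'      cases        a          b
#'      controls     c          d }
#' as used by the gene-based carrier-collapsing burden test and the
#' allelic single-variant test.
#'
#' Two p-value conventions are exposed:
#' \describe{
#'   \item{`two_sided_minlik`}{minimum-likelihood two-sided test: the sum of
#'     the point probabilities of every table with the observed margins whose
#'     probability does not exceed that of the observed table (the convention
#'     of [stats::fisher.test()]).}
#'   \item{`greater`}{one-sided upper tail, \eqn{P(X \ge a)} where \eqn{X} is
#'     hypergeometric on the observed margins; tests carrier enrichment in
#'     cases only.}
#' }
#' When one margin contains a zero cell making the table the most extreme one
#' in its tail, the two conventions coincide.
#'
#' The odds ratio is the plain cross-product \eqn{ad/bc} (not the
#' conditional-MLE estimate): `NA` when `b*c == 0` (infinite or 0/0), `0`
#' when `a*d == 0` with `b*c > 0`.  No continuity correction is applied.
#'
#' @param a,b,c,d non-negative integer cell counts (vectorised).
#' @param alternative `"two_sided_minlik"` (default) or `"greater"`.
#' @return A data.frame with columns `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(68, 14, 51, 49)                      # OR 4.67
#' fisher_exact(12, 70, 0, 100)                      # zero control carriers
#' fisher_exact(7, 75, 1, 99, alternative = "greater")
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two_sided_minlik", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  cells <- cbind(a, b, c, d)
  if (any(is.na(cells))) stop("table cells must not be NA")
  if (any(cells < 0)) stop("table cells must be non-negative")
  if (any(cells != round(cells))) stop("table cells must be integers")
  or <- odds_ratio_2x2(a, b, c, d)
  p <- vapply(seq_len(n), function(i) {
    hypergeom_2x2_p(a[i], b[i], c[i], d[i], alternative)
  }, numeric(1))
  data.frame(odds_ratio = or, p_value = p)
}

#' Cross-product odds ratio for a 2x2 table
#'
#' `ad/bc`; `NA` when `bc == 0`, `0` when `ad == 0` and `bc > 0`.
#'
#' @inheritParams fisher_exact
#' @return Numeric vector.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  or[b * c == 0] <- NA_real_
  or
}

# Exact conditional p for one table.  Margins: m = a+c carriers,
# n = b+d non-carriers, k = a+b cases; X ~ Hypergeometric(m, n, k).
# Relative tolerance on the point-probability comparison mirrors the
# usual guard against floating-point ties at the observed probability.
hypergeom_2x2_p <- function(a, b, c, d, alternative, rel_tol = 1e-7) {
  m <- a + c
  n <- b + d
  k <- a + b
  if (alternative == "greater") {
    return(stats::phyper(a - 1, m, n, k, lower.tail = FALSE))
  }
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(pr[pr <= obs * (1 + rel_tol)]))
}
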