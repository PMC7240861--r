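#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on biallelic genotype counts: given the observed
#' allele counts, the p-value is the sum of the probabilities of every
#' heterozygote count whose conditional probability does not exceed that of
#' the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts.
#' @return Exact p-value in \[0, 1\].
#' @examples
#' hwe_exact(25, 50, 25)  # perfect equilibrium, modal configuration
#' hwe_exact(10, 0, 0)    # monomorphic -> 1
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_a <- n_Aa + 2 * n_aa          # minor-allele copies (as given)
  n_A <- 2 * n - n_a
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each het count given allele counts
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) -
      lgamma(n - h - hom_rare + 1) + h * log(2) +
      lgamma(n_A + 1) + lgamma(n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}
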