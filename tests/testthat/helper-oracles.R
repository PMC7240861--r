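# Independent brute-force oracles. These deliberately avoid the code paths
# used by the package (dhyper/phyper): probabilities are assembled from
# log-binomial coefficients and normalised explicitly.

# Point probability of each table with the margins of (a, b, c, d),
# indexed by the case-carrier cell x.
oracle_table_probs <- function(a, b, c, d) {
  m <- a + c
  k <- a + b
  n_tot <- a + b + c + d
  support <- max(0, k - (n_tot - m)):min(k, m)
  logp <- lchoose(m, support) + lchoose(n_tot - m, k - support) -
    lchoose(n_tot, k)
  pr <- exp(logp - max(logp))
  list(support = support, probs = pr / sum(pr))
}

oracle_fisher_minlik <- function(a, b, c, d) {
  tp <- oracle_table_probs(a, b, c, d)
  obs <- tp$probs[tp$support == a]
  sum(tp$probs[tp$probs <= obs * (1 + 1e-7)])
}

oracle_fisher_greater <- function(a, b, c, d) {
  tp <- oracle_table_probs(a, b, c, d)
  sum(tp$probs[tp$support >= a])
}

# Exact HWE test by explicit enumeration of genotype configurations
# compatible with the observed allele counts.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- n_Aa + 2 * n_aa
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logw <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    AA <- n - h - aa
    lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logw - max(logw))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct summation of binomial coefficients.
oracle_hypergeom_upper <- function(k, set_size, pop, draws) {
  if (k == 0) return(1)
  j <- k:min(set_size, draws)
  sum(exp(lchoose(set_size, j) + lchoose(pop - set_size, draws - j) -
            lchoose(pop, draws)))
}

# Hand Benjamini-Hochberg: sorted p * n / rank, running minimum from the
# largest rank down, mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Exact rejection probability of the collapsing test under the null
# (planted odds ratio 1) at a given carrier probability.
oracle_burden_size <- function(n_cases, n_controls, p0, alpha = 0.05,
                               tail_cut = 1e-10) {
  oracle_burden_power(n_cases, n_controls, p0, or = 1, alpha = alpha,
                      tail_cut = tail_cut)
}

# Exact power of the carrier-collapsing test under the binomial carrier
# model: case carriers ~ Bin(n_cases, p1), control carriers ~
# Bin(n_controls, p0), independent.
oracle_burden_power <- function(n_cases, n_controls, p0, or, alpha = 0.05,
                                tail_cut = 1e-12) {
  odds1 <- or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  power <- 0
  for (a in 0:n_cases) {
    pa <- dbinom(a, n_cases, p1)
    if (pa < tail_cut) next
    for (cc in 0:n_controls) {
      pc <- dbinom(cc, n_controls, p0)
      if (pc < tail_cut) next
      p <- oracle_fisher_minlik(a, n_cases - a, cc, n_controls - cc)
      if (p < alpha) power <- power + pa * pc
    }
  }
  power
}
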