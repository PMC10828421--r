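#' Hardy-Weinberg exact test
#'
#' Exact conditional test for Hardy-Weinberg equilibrium at a biallelic site.
#' Conditional on the observed allele counts, the number of heterozygotes
#' under HWE follows
#' \deqn{P(n_{Aa} \mid n, n_A) = \frac{n!\,2^{n_{Aa}}}{n_{AA}!\,n_{Aa}!\,n_{aa}!}
#'   \Big/ \binom{2n}{n_A},}
#' and the two-sided p-value sums the probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed count
#' (probability-mass rule, no mid-p).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers, total >= 1).
#' @return the exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(3, 4, 3)
#' hwe_exact_test(0, 100, 0) # gross heterozygote excess
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa
  # feasible heterozygote counts share the parity of the minor allele count
  n_minor <- min(nA, 2 * n - nA)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  log_p <- lgamma(n + 1) + hets * log(2) -
    lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - nA - hets) / 2 + 1) -
    (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(2 * n - nA + 1))
  p_het <- exp(log_p - max(log_p))
  p_het <- p_het / sum(p_het)
  p_obs <- p_het[match(n_Aa, hets)]
  min(1, sum(p_het[p_het <= p_obs * (1 + 1e-9)]))
}
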