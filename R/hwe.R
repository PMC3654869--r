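#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact test conditional on the observed allele counts: the p-value is the
#' summed probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (no mid-p
#' adjustment). This is the standard behaviour of array-QC pipelines and is
#' preferred over the chi-square approximation when the rejection threshold
#' sits far in the tail.
#'
#' @param n_aa count of minor-allele homozygotes.
#' @param n_ab count of heterozygotes.
#' @param n_bb count of major-allele homozygotes.
#' @return The exact-test p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype count")
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  rare <- 2 * n_aa + n_ab
  if (rare > n) return(hwe_exact_test(n_bb, n_ab, n_aa))
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  # log P(het = h | rare allele count) up to a constant
  lp <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - aa - h
    h * log(2) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[hets == n_ab]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}
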