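# Build a genotype matrix directly from per-sample haplotype string pairs.
# Haplotypes are strings over the block SNPs; phase is collapsed exactly as
# the simulator does, so tests can construct panels with known structure.
geno_from_haps <- function(h1, h2, chrom = "1", pos0 = 1000) {
  stopifnot(length(h1) == length(h2), nchar(h1[1]) == nchar(h2[1]))
  n <- length(h1)
  w <- nchar(h1[1])
  a1 <- matrix(NA_character_, n, w)
  a2 <- matrix(NA_character_, n, w)
  for (k in seq_len(w)) {
    a1[, k] <- substr(h1, k, k)
    a2[, k] <- substr(h2, k, k)
  }
  al <- vapply(seq_len(w), function(k)
    dipclust:::infer_alleles(c(a1[, k], a2[, k])), character(2))
  snps <- data.frame(id = paste0("s", seq_len(w)), chrom = chrom,
                     pos = as.integer(pos0 + 1000 * seq_len(w)),
                     allele_a = al[1, ], allele_b = al[2, ],
                     stringsAsFactors = FALSE)
  genotype_matrix(sprintf("T%03d", seq_len(n)), snps, a1, a2)
}

# Draw n haplotype pairs from a pool (HWE random mating) and return the
# genotype matrix plus the truth pairs.
pool_cohort <- function(n, haps, freqs, seed) {
  set.seed(seed)
  h1 <- sample(haps, n, replace = TRUE, prob = freqs)
  h2 <- sample(haps, n, replace = TRUE, prob = freqs)
  list(g = geno_from_haps(h1, h2), h1 = h1, h2 = h2)
}

# Independent brute-force power-set enumeration over bitmasks: every
# nonempty subset of 1..n, ordered by size then lexicographic member tuple.
brute_force_clusters <- function(n) {
  masks <- seq_len(2^n - 1)
  sets <- lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1, 0:(n - 1))) > 0))
  key <- vapply(sets, function(s) paste(sprintf("%03d", s), collapse = ""), character(1))
  sets[order(lengths(sets), key)]
}

# Brute-force diplotype pattern count over bitmask pairs.
brute_force_pattern_count <- function(n) {
  masks <- seq_len(2^n - 1)
  stars <- length(masks)
  pairs <- 0L
  for (i in seq_along(masks)) for (j in seq_along(masks)) {
    if (j > i && bitwAnd(masks[i], masks[j]) == 0) pairs <- pairs + 1L
  }
  stars + pairs
}

block1 <- function(g) list(snp_start = 1, snp_end = ncol(g$a1))
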