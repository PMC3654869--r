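#' @keywords internal
#' Enumerate haplotype pairs consistent with one multi-SNP genotype
#'
#' `g1`, `g2` are the two alleles at each SNP (NA = missing); `alleles` is a
#' list of the possible alleles at each SNP. Missing sites are marginalised:
#' every allele combination is allowed there. Returns a two-column character
#' matrix of unordered haplotype-string pairs (hap1 <= hap2).
consistent_pairs <- function(g1, g2, alleles) {
  w <- length(g1)
  opts <- vector("list", w)
  for (k in seq_len(w)) {
    if (is.na(g1[k])) {
      al <- alleles[[k]]
      opts[[k]] <- as.matrix(expand.grid(al, al, stringsAsFactors = FALSE,
                                         KEEP.OUT.ATTRS = FALSE))
    } else if (g1[k] == g2[k]) {
      opts[[k]] <- matrix(c(g1[k], g2[k]), 1, 2)
    } else {
      opts[[k]] <- matrix(c(g1[k], g2[k], g2[k], g1[k]), 2, 2, byrow = TRUE)
    }
  }
  idx <- expand.grid(lapply(opts, function(o) seq_len(nrow(o))),
                     KEEP.OUT.ATTRS = FALSE)
  h1 <- apply(idx, 1, function(r) paste(vapply(seq_len(w), function(k)
    opts[[k]][r[k], 1], character(1)), collapse = ""))
  h2 <- apply(idx, 1, function(r) paste(vapply(seq_len(w), function(k)
    opts[[k]][r[k], 2], character(1)), collapse = ""))
  swap <- h1 > h2
  pair <- cbind(ifelse(swap, h2, h1), ifelse(swap, h1, h2))
  unique(pair)
}

block_genotype_patterns <- function(g, block) {
  ki <- seq(block$snp_start, block$snp_end)
  a1 <- g$a1[, ki, drop = FALSE]
  a2 <- g$a2[, ki, drop = FALSE]
  alleles <- lapply(ki, function(k) {
    al <- c(g$snps$allele_a[k], g$snps$allele_b[k])
    al[!is.na(al)]
  })
  key <- apply(cbind(a1, a2), 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  all_missing <- rowSums(!is.na(a1)) == 0
  list(a1 = a1, a2 = a2, alleles = alleles, key = key, all_missing = all_missing)
}

#' Estimate block haplotype frequencies by EM
#'
#' Standard multilocus expectation-maximisation over unphased genotypes.
#' The E-step distributes each sample's mass over the haplotype pairs
#' consistent with its genotypes (missing sites marginalised, not imputed),
#' proportional to the current pair probabilities (2 f_a f_b for a
#' heterozygous pair, f_a^2 for a homozygous one); the M-step re-estimates
#' frequencies from the expected haplotype counts. Initialisation is
#' uniform over all haplotypes consistent with the data, so the result is
#' deterministic. Samples with every block SNP missing are excluded.
#'
#' @param g a [genotype_matrix()].
#' @param block an LD block (list/row with `snp_start`, `snp_end`, 1-based
#'   inclusive SNP indices), e.g. one row of a block table.
#' @param tol convergence tolerance on the maximum absolute frequency change
#'   (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000); non-convergence
#'   produces a warning with the final change, and the current estimate is
#'   still returned.
#' @return data.frame with columns `hap` (allele string, one character per
#'   block SNP) and `freq`, restricted to haplotypes with positive final
#'   frequency and sorted by descending frequency (ties by allele string).
#'   Attributes: `loglik` (per-iteration trajectory), `iterations`,
#'   `converged`.
#' @export
em_frequencies <- function(g, block, tol = 1e-8, max_iter = 1000) {
  pat <- block_genotype_patterns(g, block)
  use <- !pat$all_missing
  if (!any(use)) stop("no sample has any non-missing genotype in the block")
  key <- pat$key[use]
  tab <- table(key)
  ukeys <- names(tab)
  cnt <- as.numeric(tab)
  first <- match(ukeys, key)
  w <- ncol(pat$a1)
  pairs <- lapply(first, function(i)
    consistent_pairs(pat$a1[use, , drop = FALSE][i, ],
                     pat$a2[use, , drop = FALSE][i, ], pat$alleles))
  haps <- sort(unique(unlist(pairs)))
  pair_idx <- lapply(pairs, function(p)
    cbind(match(p[, 1], haps), match(p[, 2], haps)))
  nh <- length(haps)
  f <- rep(1 / nh, nh)
  n2 <- 2 * sum(cnt)
  ll_trace <- numeric(0)
  converged <- FALSE
  delta <- NA_real_
  for (it in seq_len(max_iter)) {
    counts <- numeric(nh)
    ll <- 0
    for (p in seq_along(pair_idx)) {
      ij <- pair_idx[[p]]
      wts <- f[ij[, 1]] * f[ij[, 2]] * ifelse(ij[, 1] == ij[, 2], 1, 2)
      s <- sum(wts)
      if (s <= 0) { # degenerate: fall back to uniform over this sample's pairs
        wts <- rep(1, nrow(ij)); s <- nrow(ij)
      }
      post <- cnt[p] * wts / s
      for (r in seq_len(nrow(ij))) {
        counts[ij[r, 1]] <- counts[ij[r, 1]] + post[r]
        counts[ij[r, 2]] <- counts[ij[r, 2]] + post[r]
      }
      ll <- ll + cnt[p] * log(s)
    }
    ll_trace <- c(ll_trace, ll)
    f_new <- counts / n2
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")")
  keep <- f > 0
  out <- data.frame(hap = haps[keep], freq = f[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$hap), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "loglik") <- ll_trace
  attr(out, "iterations") <- length(ll_trace)
  attr(out, "converged") <- converged
  out
}

#' Assign each sample its most likely haplotype pair
#'
#' For every sample with at least one non-missing block SNP, enumerates the
#' haplotype pairs consistent with its genotypes, scores each by the EM
#' frequencies (2 f_a f_b for a heterozygous pair, f_a^2 otherwise) and
#' returns the highest-scoring pair with its normalised posterior. Ties are
#' broken by the lexicographically smallest haplotype-index pair, so output
#' is deterministic. Samples with all block SNPs missing are omitted.
#'
#' @param g a [genotype_matrix()].
#' @param block an LD block (`snp_start`, `snp_end`).
#' @param haps haplotype table from [em_frequencies()] on the same block.
#' @return data.frame with columns `sample_id`, `hap1`, `hap2` (indices into
#'   `haps`, `hap1 <= hap2`), `hap1_str`, `hap2_str`, `posterior`.
#' @export
phase_samples <- function(g, block, haps) {
  pat <- block_genotype_patterns(g, block)
  use <- which(!pat$all_missing)
  if (!length(use))
    return(data.frame(sample_id = character(), hap1 = integer(), hap2 = integer(),
                      hap1_str = character(), hap2_str = character(),
                      posterior = numeric(), stringsAsFactors = FALSE))
  key <- pat$key[use]
  ukeys <- unique(key)
  first <- match(ukeys, key)
  best <- lapply(first, function(i) {
    p <- consistent_pairs(pat$a1[use[i], ], pat$a2[use[i], ], pat$alleles)
    i1 <- match(p[, 1], haps$hap)
    i2 <- match(p[, 2], haps$hap)
    ok <- !is.na(i1) & !is.na(i2)
    if (!any(ok)) return(NULL) # only explainable by zero-frequency haplotypes
    i1 <- i1[ok]; i2 <- i2[ok]
    lo <- pmin(i1, i2); hi <- pmax(i1, i2)
    wts <- haps$freq[lo] * haps$freq[hi] * ifelse(lo == hi, 1, 2)
    post <- wts / sum(wts)
    ord <- order(-post, lo, hi)
    c(lo[ord[1]], hi[ord[1]], post[ord[1]])
  })
  rows <- match(key, ukeys)
  keep <- !vapply(best, is.null, logical(1))[rows]
  b <- do.call(rbind, best[rows[keep]])
  data.frame(sample_id = g$samples[use][keep],
             hap1 = as.integer(b[, 1]), hap2 = as.integer(b[, 2]),
             hap1_str = haps$hap[b[, 1]], hap2_str = haps$hap[b[, 2]],
             posterior = b[, 3], stringsAsFactors = FALSE)
}

#' Split haplotypes into common and rare sets by a frequency threshold
#'
#' The common set H contains the haplotypes with frequency strictly greater
#' than `threshold`, ordered by descending frequency (ties by allele
#' string); everything else is rare. H is the set from which haplotype
#' clusters are enumerated; rare haplotypes remain part of the "star"
#' universe in versus-star patterns.
#'
#' @param haps haplotype table from [em_frequencies()].
#' @param threshold frequency threshold (default 0.01).
#' @return list with data.frame elements `common` and `rare`.
#' @export
common_haplotypes <- function(haps, threshold = 0.01) {
  ord <- order(-haps$freq, haps$hap)
  haps <- haps[ord, , drop = FALSE]
  is_common <- haps$freq > threshold
  if (!any(is_common))
    stop("no haplotype exceeds the frequency threshold ", threshold)
  common <- haps[is_common, , drop = FALSE]
  rare <- haps[!is_common, , drop = FALSE]
  rownames(common) <- rownames(rare) <- NULL
  list(common = common, rare = rare)
}
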