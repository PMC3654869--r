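two_locus_freqs <- function(g, i, j) {
  sub <- subset_genotypes(g, snps = sort(c(i, j)))
  if (any(is.na(sub$snps$allele_b)))
    stop("LD undefined for monomorphic SNP ", sub$snps$id[is.na(sub$snps$allele_b)][1])
  haps <- em_frequencies(sub, list(snp_start = 1, snp_end = 2), tol = 1e-10)
  list(haps = haps, snps = sub$snps, sub = sub)
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' Two-locus haplotype frequencies are estimated by EM over double
#' heterozygotes; D' = |D| / Dmax and r^2 = D^2 / (pA pa pB pb) follow.
#' The D' confidence interval is obtained from a likelihood profile over a
#' 101-point grid on the unit interval (allele frequencies held at their
#' estimates):
#' the bounds are the grid points where the cumulative normalised
#' likelihood mass crosses 5% and 95%, i.e. the central 90% mass.
#'
#' @param g a [genotype_matrix()].
#' @param i,j SNP indices (1-based); the result is symmetric in (i, j).
#' @return list with `d_prime`, `r2`, `ci_low`, `ci_high`, and `n_gametes`
#'   (two-locus haplotypes with estimated frequency >= 0.01).
#' @export
pairwise_ld <- function(g, i, j) {
  if (i == j) stop("i and j must differ")
  tl <- two_locus_freqs(g, i, j)
  a1 <- tl$snps$allele_a[1]
  a2 <- tl$snps$allele_a[2]
  fr <- setNames(tl$haps$freq, tl$haps$hap)
  pf <- function(h) if (h %in% names(fr)) unname(fr[h]) else 0
  b1 <- tl$snps$allele_b[1]; b2 <- tl$snps$allele_b[2]
  p11 <- pf(paste0(a1, a2))
  pA <- p11 + pf(paste0(a1, b2))
  pB <- p11 + pf(paste0(b1, a2))
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax <= 0) 0 else min(1, abs(D) / dmax)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom <= 0) 0 else min(1, D^2 / denom)
  ci <- dprime_ci(tl$sub, pA, pB, sign(D))
  list(d_prime = d_prime, r2 = r2, ci_low = ci[1], ci_high = ci[2],
       n_gametes = sum(tl$haps$freq >= 0.01))
}

dprime_ci <- function(sub, pA, pB, dsign) {
  # 3x3 two-locus genotype counts: doses of allele_a at each SNP
  d1 <- (sub$a1[, 1] == sub$snps$allele_a[1]) + (sub$a2[, 1] == sub$snps$allele_a[1])
  d2 <- (sub$a1[, 2] == sub$snps$allele_a[2]) + (sub$a2[, 2] == sub$snps$allele_a[2])
  ok <- !is.na(d1) & !is.na(d2)
  if (!any(ok)) stop("no doubly genotyped sample for the SNP pair")
  cnt <- table(factor(d1[ok], 0:2), factor(d2[ok], 0:2))
  if (dsign == 0) dsign <- 1
  grid <- seq(0, 1, length.out = 101)
  ll <- vapply(grid, function(dp) {
    dmax <- if (dsign >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
    Ds <- dsign * dp * dmax
    p <- pmax(c(pA * pB + Ds, pA * (1 - pB) - Ds,
                (1 - pA) * pB - Ds, (1 - pA) * (1 - pB) + Ds), 1e-12)
    # genotype probabilities indexed [dose1+1, dose2+1]
    P <- matrix(c(p[4]^2, 2 * p[4] * p[3], p[3]^2,
                  2 * p[4] * p[2], 2 * p[1] * p[4] + 2 * p[2] * p[3], 2 * p[1] * p[3],
                  p[2]^2, 2 * p[1] * p[2], p[1]^2), 3, 3, byrow = TRUE)
    sum(cnt * log(P))
  }, numeric(1))
  L <- exp(ll - max(ll))
  cs <- cumsum(L) / sum(L)
  c(grid[which(cs >= 0.05)[1]], grid[which(cs >= 0.95)[1]])
}

#' Pairwise LD statistics for all SNP pairs
#'
#' @param g a [genotype_matrix()].
#' @return list of m x m matrices `d_prime`, `r2`, `ci_low`, `ci_high`,
#'   `n_gametes` (diagonal NA).
#' @export
ld_matrix <- function(g) {
  m <- nrow(g$snps)
  mk <- function() matrix(NA_real_, m, m)
  out <- list(d_prime = mk(), r2 = mk(), ci_low = mk(), ci_high = mk(),
              n_gametes = mk())
  if (m < 2) return(out)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ld <- pairwise_ld(g, i, j)
    for (nm in names(out)) out[[nm]][i, j] <- out[[nm]][j, i] <- ld[[nm]]
  }
  out
}

new_block_table <- function(starts, ends, method) {
  data.frame(snp_start = as.integer(starts), snp_end = as.integer(ends),
             method = rep(method, length(starts)), stringsAsFactors = FALSE)
}

#' LD blocks by the confidence-interval (Gabriel-style) rule
#'
#' A SNP pair is in "strong LD" when its D' CI satisfies
#' `ci_high >= 0.98` and `ci_low >= 0.70`, and shows "strong recombination"
#' when `ci_high < 0.90`; pairs in either class are informative. A candidate
#' block is a SNP range in which at least `frac` (default 95%) of the
#' informative pairs are in strong LD. Maximal non-overlapping blocks are
#' chosen greedily longest-first, ties broken by leftmost start.
#'
#' @param g a [genotype_matrix()].
#' @param ld optional precomputed [ld_matrix()].
#' @param strong_high,strong_low,recomb_high,frac thresholds of the rule.
#' @return data.frame of blocks (`snp_start`, `snp_end` 1-based inclusive,
#'   `method`); empty when no block is found.
#' @export
gabriel_blocks <- function(g, ld = NULL, strong_high = 0.98, strong_low = 0.70,
                           recomb_high = 0.90, frac = 0.95) {
  m <- nrow(g$snps)
  if (m < 2) return(new_block_table(integer(), integer(), "gabriel"))
  if (is.null(ld)) ld <- ld_matrix(g)
  strong <- ld$ci_high >= strong_high & ld$ci_low >= strong_low
  recomb <- ld$ci_high < recomb_high
  cand <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    idx <- t(utils::combn(i:j, 2))
    s <- strong[idx]
    inf <- s | recomb[idx]
    if (sum(inf) > 0 && sum(s) / sum(inf) >= frac)
      cand[[length(cand) + 1]] <- c(i, j)
  }
  select_blocks(cand, "gabriel")
}

select_blocks <- function(cand, method) {
  if (!length(cand)) return(new_block_table(integer(), integer(), method))
  cd <- do.call(rbind, cand)
  cd <- cd[order(-(cd[, 2] - cd[, 1]), cd[, 1]), , drop = FALSE]
  used <- integer(0)
  starts <- integer(0); ends <- integer(0)
  for (r in seq_len(nrow(cd))) {
    rng <- cd[r, 1]:cd[r, 2]
    if (!any(rng %in% used)) {
      starts <- c(starts, cd[r, 1]); ends <- c(ends, cd[r, 2])
      used <- c(used, rng)
    }
  }
  ord <- order(starts)
  new_block_table(starts[ord], ends[ord], method)
}

#' LD blocks by the four-gamete rule
#'
#' Extends a block from the left while every SNP pair inside it shows fewer
#' than four two-locus gametes with estimated frequency >= `min_freq`; a
#' fourth gamete breaks the block.
#'
#' @param g a [genotype_matrix()].
#' @param ld optional precomputed [ld_matrix()].
#' @param min_freq gamete frequency needed to count as observed (default 0.01).
#' @return data.frame of blocks.
#' @export
four_gamete_blocks <- function(g, ld = NULL, min_freq = 0.01) {
  m <- nrow(g$snps)
  if (m < 2) return(new_block_table(integer(), integer(), "four_gamete"))
  if (is.null(ld)) ld <- ld_matrix(g)
  ok <- ld$n_gametes < 4
  starts <- integer(0); ends <- integer(0)
  i <- 1
  while (i < m) {
    j <- i
    while (j < m && all(ok[i:j, j + 1])) j <- j + 1
    if (j > i) {
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1
    } else i <- i + 1
  }
  new_block_table(starts, ends, "four_gamete")
}

#' LD blocks by the solid-spine rule
#'
#' A block is a maximal run in which D' between the first SNP and every
#' later SNP, and between the last SNP and every earlier SNP, is at least
#' `min_dprime`.
#'
#' @param g a [genotype_matrix()].
#' @param ld optional precomputed [ld_matrix()].
#' @param min_dprime spine threshold (default 0.80).
#' @return data.frame of blocks.
#' @export
solid_spine_blocks <- function(g, ld = NULL, min_dprime = 0.80) {
  m <- nrow(g$snps)
  if (m < 2) return(new_block_table(integer(), integer(), "solid_spine"))
  if (is.null(ld)) ld <- ld_matrix(g)
  dp <- ld$d_prime
  starts <- integer(0); ends <- integer(0)
  i <- 1
  while (i < m) {
    found <- 0L
    for (j in m:(i + 1)) {
      if (all(dp[i, (i + 1):j] >= min_dprime) && all(dp[j, i:(j - 1)] >= min_dprime)) {
        found <- j
        break
      }
    }
    if (found) {
      starts <- c(starts, i); ends <- c(ends, found)
      i <- found + 1
    } else i <- i + 1
  }
  new_block_table(starts, ends, "solid_spine")
}

#' Detect LD blocks by a named method
#'
#' @param g a [genotype_matrix()].
#' @param method one of "gabriel", "four_gamete", "solid_spine".
#' @param ld optional precomputed [ld_matrix()].
#' @return data.frame of blocks.
#' @export
detect_blocks <- function(g, method = c("gabriel", "four_gamete", "solid_spine"),
                          ld = NULL) {
  method <- match.arg(method)
  switch(method,
         gabriel = gabriel_blocks(g, ld),
         four_gamete = four_gamete_blocks(g, ld),
         solid_spine = solid_spine_blocks(g, ld))
}

#' Write a block table as TSV
#'
#' Columns: block id, chromosome, start bp, end bp (1-based inclusive),
#' comma-separated SNP ids.
#' @param blocks block data.frame from [detect_blocks()].
#' @param g the `genotype_matrix` the indices refer to.
#' @param path output path.
#' @export
write_blocks_tsv <- function(blocks, g, path) {
  rows <- lapply(seq_len(nrow(blocks)), function(b) {
    ki <- blocks$snp_start[b]:blocks$snp_end[b]
    data.frame(block = paste0("b", b), chrom = g$snps$chrom[ki[1]],
               start_bp = g$snps$pos[ki[1]], end_bp = g$snps$pos[ki[length(ki)]],
               snps = paste(g$snps$id[ki], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block = character(), chrom = character(), start_bp = integer(),
               end_bp = integer(), snps = character())
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(out)
}
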