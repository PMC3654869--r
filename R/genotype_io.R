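#' Construct a genotype matrix
#'
#' Container for unphased biallelic SNP genotypes: per (sample, SNP) an
#' unordered allele pair or missing. Calls are stored as two character
#' matrices with the pair sorted within each cell (`a1 <= a2`); a missing
#' call has `NA` in both.
#'
#' @param samples character vector of sample ids (unique).
#' @param snps data.frame with columns `id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`; one row per SNP, ordered by position within chromosome.
#'   `allele_b` may be `NA` for a monomorphic SNP.
#' @param a1,a2 character matrices (samples x SNPs) holding the two alleles
#'   of each call, `NA` for missing.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, snps, a1, a2) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids")
  if (!all(c("id", "chrom", "pos", "allele_a", "allele_b") %in% names(snps)))
    stop("snps must have columns id, chrom, pos, allele_a, allele_b")
  if (nrow(a1) != length(samples) || ncol(a1) != nrow(snps) ||
      !identical(dim(a1), dim(a2)))
    stop("call matrix dimensions do not match samples / snps")
  # strictly increasing position within each chromosome
  for (chr in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == chr]
    if (any(diff(p) <= 0)) stop("SNP positions must strictly increase within chromosome ", chr)
  }
  # normalize pair order and missingness
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  swap <- !miss & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  for (k in seq_len(nrow(snps))) {
    obs <- unique(c(a1[, k], a2[, k]))
    obs <- obs[!is.na(obs)]
    valid <- c(snps$allele_a[k], snps$allele_b[k])
    if (length(setdiff(obs, valid)))
      stop("SNP ", snps$id[k], " has calls outside its declared alleles")
  }
  dimnames(a1) <- dimnames(a2) <- list(samples, snps$id)
  structure(list(samples = samples, snps = snps, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$snps), "SNPs\n")
  cat("  missing calls:", sum(is.na(x$a1)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$snps))

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g a `genotype_matrix`.
#' @param samples,snps index vectors (integer or logical); default keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(g$samples) else samples
  ki <- if (is.null(snps)) seq_len(nrow(g$snps)) else snps
  genotype_matrix(g$samples[si], g$snps[ki, , drop = FALSE],
                  g$a1[si, ki, drop = FALSE], g$a2[si, ki, drop = FALSE])
}

infer_alleles <- function(obs) {
  obs <- sort(unique(obs[!is.na(obs)]))
  if (length(obs) > 2) stop("more than two alleles observed: ", paste(obs, collapse = ","))
  c(obs, NA_character_)[1:2]
}

#' Read PLINK PED/MAP text files
#'
#' Parses the whitespace-delimited PLINK text dialect: MAP gives one SNP per
#' line (chrom, id, cM, bp); PED gives six leading fields (family, sample,
#' father, mother, sex, phenotype) followed by two alleles per SNP, with "0"
#' meaning a missing allele. Family/parent/sex/phenotype fields are parsed
#' but ignored. A half-call (one allele missing) is treated as fully missing.
#' Alleles at each SNP are inferred from the observed data.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos")
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  samples <- character(n)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("PED line ", i, ": expected ", 6 + 2 * m, " fields, found ", length(f))
    samples[i] <- f[2]
    x <- f[-(1:6)]
    h1 <- x[seq(1, 2 * m, by = 2)]
    h2 <- x[seq(2, 2 * m, by = 2)]
    h1[h1 == "0"] <- NA_character_
    h2[h2 == "0"] <- NA_character_
    half <- xor(is.na(h1), is.na(h2))
    h1[half] <- NA_character_
    h2[half] <- NA_character_
    a1[i, ] <- h1
    a2[i, ] <- h2
  }
  al <- vapply(seq_len(m), function(k) {
    tryCatch(infer_alleles(c(a1[, k], a2[, k])),
             error = function(e) stop("SNP ", map$id[k], ": ", conditionMessage(e)))
  }, character(2))
  snps <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                     allele_a = al[1, ], allele_b = al[2, ],
                     stringsAsFactors = FALSE)
  genotype_matrix(samples, snps, a1, a2)
}

#' Write PLINK PED/MAP text files
#'
#' Inverse of [read_ped_map()]: missing calls become `0 0`, map distance is
#' written as 0 cM.
#'
#' @param g a `genotype_matrix`.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  map <- data.frame(g$snps$chrom, g$snps$id, 0, g$snps$pos)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- length(g$samples)
  m <- nrow(g$snps)
  geno <- matrix("0", n, 2 * m)
  geno[, seq(1, 2 * m, by = 2)] <- ifelse(is.na(g$a1), "0", g$a1)
  geno[, seq(2, 2 * m, by = 2)] <- ifelse(is.na(g$a2), "0", g$a2)
  out <- cbind(g$samples, g$samples, "0", "0", "0", "-9", geno)
  writeLines(apply(out, 1, paste, collapse = " "), ped_path)
  invisible(NULL)
}

#' Read unphased genotypes from a VCF file
#'
#' Maps GT fields to allele pairs; both unphased (`/`) and phased (`|`)
#' separators are accepted and phase is ignored. Requires the `vcfR` package.
#'
#' @param vcf_path path to an (uncompressed or gzipped) VCF.
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(vcf_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  m <- nrow(gt)
  samples <- colnames(gt)
  n <- length(samples)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  for (k in seq_len(m)) {
    alleles <- c(fix[k, "REF"], strsplit(fix[k, "ALT"], ",")[[1]])
    parts <- strsplit(gt[k, ], "[/|]")
    for (i in seq_len(n)) {
      p <- parts[[i]]
      if (length(p) == 2 && !any(p == ".") && !any(is.na(p))) {
        a1[i, k] <- alleles[as.integer(p[1]) + 1]
        a2[i, k] <- alleles[as.integer(p[2]) + 1]
      }
    }
  }
  al <- vapply(seq_len(m), function(k) infer_alleles(c(a1[, k], a2[, k])), character(2))
  snps <- data.frame(id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                 paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
                     chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     allele_a = al[1, ], allele_b = al[2, ],
                     stringsAsFactors = FALSE)
  genotype_matrix(samples, snps, a1, a2)
}

#' Per-SNP call rate
#' @param g a `genotype_matrix`.
#' @return numeric vector, fraction of samples with a non-missing call.
#' @export
snp_call_rate <- function(g) colMeans(!is.na(g$a1))

#' Per-SNP minor allele frequency
#'
#' Computed over non-missing calls only; 0 for a monomorphic SNP.
#' @param g a `genotype_matrix`.
#' @return numeric vector of MAFs.
#' @export
snp_maf <- function(g) {
  vapply(seq_len(nrow(g$snps)), function(k) {
    x <- c(g$a1[, k], g$a2[, k])
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    fa <- mean(x == g$snps$allele_a[k])
    min(fa, 1 - fa)
  }, numeric(1))
}

snp_genotype_counts <- function(g, k) {
  # counts ordered (a-homo, het, b-homo) for SNP k, allele_a being "a"
  a <- g$snps$allele_a[k]
  n_a <- (g$a1[, k] == a) + (g$a2[, k] == a)
  n_a <- n_a[!is.na(n_a)]
  c(sum(n_a == 2), sum(n_a == 1), sum(n_a == 0))
}

#' Apply SNP quality-control filters
#'
#' Retains exactly the SNPs passing all three standard array-QC filters:
#' call rate at least `min_call`, minor allele frequency at least `min_maf`,
#' and Hardy-Weinberg exact-test p-value at least `hwe_alpha`. The sample
#' set is unchanged. Filtering is idempotent and preserves SNP order.
#'
#' @param g a `genotype_matrix`.
#' @param min_call minimum call rate (default 0.95).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param hwe_alpha minimum HWE exact-test p-value (default 1e-6).
#' @return A filtered `genotype_matrix`; a warning is emitted if no SNP
#'   survives.
#' @export
filter_snps <- function(g, min_call = 0.95, min_maf = 0.05, hwe_alpha = 1e-6) {
  cr <- snp_call_rate(g)
  maf <- snp_maf(g)
  hwe <- vapply(seq_len(nrow(g$snps)), function(k) {
    cnt <- snp_genotype_counts(g, k)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  keep <- cr >= min_call & maf >= min_maf & hwe >= hwe_alpha
  if (!any(keep)) warning("no SNPs pass the QC filters")
  subset_genotypes(g, snps = which(keep))
}

#' Read a phenotype/covariate table
#'
#' Reads a tab-separated table with a header row. Cells that do not parse
#' as numbers (e.g. "NA", empty) become missing. A binary trait must contain
#' only 0/1/missing.
#'
#' @param path path to the TSV file.
#' @param trait_name name of the trait column.
#' @param covariate_names character vector of covariate column names
#'   (may be empty).
#' @param id_name name of the sample-id column (default: first column).
#' @return data.frame with columns `sample_id`, `trait`, and one column per
#'   covariate.
#' @export
read_phenotypes <- function(path, trait_name, covariate_names = character(),
                            id_name = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (is.null(id_name)) id_name <- names(tab)[1]
  need <- c(id_name, trait_name, covariate_names)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("phenotype file lacks column(s): ", paste(missing_cols, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(sample_id = tab[[id_name]], trait = num(tab[[trait_name]]),
                    stringsAsFactors = FALSE)
  for (cv in covariate_names) out[[cv]] <- num(tab[[cv]])
  out
}

#' Write a phenotype/covariate table
#' @param ph data.frame as returned by [read_phenotypes()].
#' @param path output path.
#' @param trait_name column name to use for the trait in the file.
#' @export
write_phenotypes <- function(ph, path, trait_name = "trait") {
  out <- ph
  names(out)[names(out) == "trait"] <- trait_name
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}

#' Align genotype and phenotype samples by id intersection
#'
#' Keeps the samples present in both inputs (genotype order); drops the rest
#' with a message giving the dropped counts.
#'
#' @param g a `genotype_matrix`.
#' @param ph a phenotype data.frame with a `sample_id` column.
#' @return list with elements `genotypes` and `phenotypes`, row-aligned.
#' @export
align_samples <- function(g, ph) {
  common <- intersect(g$samples, ph$sample_id)
  d_g <- length(g$samples) - length(common)
  d_p <- length(unique(ph$sample_id)) - length(common)
  if (d_g || d_p)
    message("align_samples: dropped ", d_g, " genotype-only and ", d_p,
            " phenotype-only samples")
  g2 <- subset_genotypes(g, samples = match(common, g$samples))
  ph2 <- ph[match(common, ph$sample_id), , drop = FALSE]
  rownames(ph2) <- NULL
  list(genotypes = g2, phenotypes = ph2)
}
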