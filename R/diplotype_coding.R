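star_label <- function(label) sub("_H", "_OH", label, fixed = TRUE)

#' Generate all diplotype patterns from a cluster enumeration
#'
#' A diplotype pattern is a tested hypothesis pairing haplotype clusters:
#' either one cluster versus "star" (every other haplotype, including rare
#' ones below the frequency threshold), or two disjoint clusters. For n
#' common haplotypes this yields 2^n - 1 versus-star patterns plus
#' (3^n - 2^(n+1) + 1) / 2 disjoint unordered pairs. Versus-star patterns
#' come first in cluster-enumeration order; pairs follow, ordered by size
#' signature (smaller cluster first) and then lexicographically by member
#' indices.
#'
#' @param HS cluster list from [enumerate_clusters()].
#' @return list of patterns; each is a list with `kind`
#'   (`"versus_star"` or `"versus_cluster"`), `c1`, `c2` (a cluster, or
#'   `NULL` for star) and `id` (e.g. `"b1_H12/b1_OH12"`).
#' @export
enumerate_patterns <- function(HS) {
  stars <- lapply(HS, function(cl)
    list(kind = "versus_star", c1 = cl, c2 = NULL,
         id = paste0(cl$label, "/", star_label(cl$label))))
  pairs <- list()
  np <- length(HS)
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (j <= i) next
      if (length(intersect(HS[[i]]$members, HS[[j]]$members))) next
      pairs[[length(pairs) + 1]] <- list(
        kind = "versus_cluster", c1 = HS[[i]], c2 = HS[[j]],
        id = paste0(HS[[i]]$label, "/", HS[[j]]$label))
    }
  }
  if (length(pairs)) {
    key <- function(cl) paste(sprintf("%03d", cl$members), collapse = "")
    ord <- order(vapply(pairs, function(p) length(p$c1$members), integer(1)),
                 vapply(pairs, function(p) length(p$c2$members), integer(1)),
                 vapply(pairs, function(p) key(p$c1), character(1)),
                 vapply(pairs, function(p) key(p$c2), character(1)))
    pairs <- pairs[ord]
  }
  c(stars, pairs)
}

#' Closed-form diplotype pattern count
#'
#' @param n number of common haplotypes.
#' @return (2^n - 1) + (3^n - 2^(n+1) + 1) / 2.
#' @export
pattern_count <- function(n) (2^n - 1) + (3^n - 2^(n + 1) + 1) / 2

#' Recode assigned haplotype pairs under one diplotype pattern
#'
#' For a versus-star pattern the universe is every haplotype (rare ones
#' included), so each phased sample gets a dose in 0/1/2 counting its
#' haplotypes inside the cluster. For a cluster-versus-cluster pattern a
#' sample is included only when both of its haplotypes lie in the union of
#' the two clusters; otherwise its dose is missing. The dose counts copies
#' of `pattern$c1`; [assign_minor_major()] orients it to the minor side.
#'
#' @param pattern one pattern from [enumerate_patterns()].
#' @param diplos phased samples from [phase_samples()].
#' @param H common-haplotype data.frame (column `hap`) the pattern indices
#'   refer to.
#' @return data.frame with `sample_id` and `dose` (0/1/2 or NA).
#' @export
code_samples <- function(pattern, diplos, H) {
  c1 <- H$hap[pattern$c1$members]
  in1 <- (diplos$hap1_str %in% c1) + (diplos$hap2_str %in% c1)
  if (pattern$kind == "versus_star") {
    dose <- in1
  } else {
    c2 <- H$hap[pattern$c2$members]
    both_in <- (diplos$hap1_str %in% c(c1, c2)) & (diplos$hap2_str %in% c(c1, c2))
    dose <- ifelse(both_in, in1, NA_integer_)
  }
  data.frame(sample_id = diplos$sample_id, dose = as.integer(dose),
             stringsAsFactors = FALSE)
}

#' Orient a coded pattern to its minor cluster
#'
#' The minor side is the one carrying the smaller total haplotype dose over
#' the included samples (a tie keeps `c1` as minor, with a message). Doses
#' are reflected (2 - dose) when the minor side is the second cluster, so
#' the returned dose always counts minor-cluster copies. The counts triplet
#' is (minor-homozygote, heterozygote, major-homozygote).
#'
#' @param pattern one pattern from [enumerate_patterns()].
#' @param coded output of [code_samples()] for that pattern.
#' @return list with `minor_label`, `major_label`, `counts` (length-3
#'   integer), `dose` (oriented, NA preserved), `n_used`.
#' @export
assign_minor_major <- function(pattern, coded) {
  inc <- !is.na(coded$dose)
  if (!any(inc)) stop("no sample is covered by the pattern")
  d <- coded$dose
  lab1 <- pattern$c1$label
  lab2 <- if (pattern$kind == "versus_star") star_label(lab1) else pattern$c2$label
  sum1 <- sum(d[inc])
  sum2 <- 2 * sum(inc) - sum1
  if (sum1 > sum2) {
    d <- 2L - d
    minor <- lab2; major <- lab1
  } else {
    if (sum1 == sum2) message("minor/major tie for ", pattern$id,
                              "; keeping ", lab1, " as minor")
    minor <- lab1; major <- lab2
  }
  counts <- c(sum(d[inc] == 2), sum(d[inc] == 1), sum(d[inc] == 0))
  list(minor_label = minor, major_label = major, counts = as.integer(counts),
       dose = d, n_used = sum(inc))
}

#' Export coded patterns as pseudo-SNPs in PED/MAP format
#'
#' Each pattern becomes one biallelic pseudo-marker: minor cluster as
#' allele "A", major as "B" (so doses 2/1/0 map to `A A`, `A B`, `B B`),
#' and `0 0` for samples the pattern excludes. The output is valid PLINK
#' text input, allowing an external regression cross-check.
#'
#' @param oriented list of [assign_minor_major()] results, one per pattern.
#' @param patterns the matching pattern list (for ids).
#' @param sample_ids sample ids, aligned with the coded doses.
#' @param ped_path,map_path output paths.
#' @export
export_patterns_ped <- function(oriented, patterns, sample_ids, ped_path, map_path) {
  stopifnot(length(oriented) == length(patterns))
  map <- data.frame("0", vapply(patterns, `[[`, character(1), "id"),
                    0, seq_along(patterns))
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  geno <- vapply(oriented, function(o) {
    c("B B", "A B", "A A")[o$dose + 1L]
  }, character(length(sample_ids)))
  geno[is.na(geno)] <- "0 0"
  out <- cbind(sample_ids, sample_ids, "0", "0", "0", "-9",
               matrix(geno, nrow = length(sample_ids)))
  writeLines(apply(out, 1, paste, collapse = " "), ped_path)
  invisible(NULL)
}
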