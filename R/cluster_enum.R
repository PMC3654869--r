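#' Enumerate all haplotype clusters of a common-haplotype set
#'
#' A haplotype cluster is any nonempty subset of the block's common
#' haplotypes, treated as one pseudo-allele. Every such subset is produced
#' exactly once (2^n - 1 clusters for n common haplotypes), ordered by
#' ascending subset size and, within a size, by lexicographic order of the
#' member-index tuples. Labels `H1 .. H{2^n-1}` follow that order, so the
#' enumeration is byte-stable for a given input ordering. Note the labels
#' depend on how the input haplotypes are ordered (here: the descending
#' frequency order of [common_haplotypes()]), so they are reproducible
#' within this convention but not comparable across tools that order H
#' differently.
#'
#' @param H data.frame of common haplotypes (column `hap`; typically the
#'   `common` element of [common_haplotypes()]), or a character vector of
#'   haplotype strings.
#' @param block_id integer used in the `b{block}_H{k}` labels (default 1).
#' @return list of clusters; each is a list with `members` (integer indices
#'   into H), `haps` (member haplotype strings) and `label`
#'   (`b{block}_H{k}`).
#' @export
enumerate_clusters <- function(H, block_id = 1) {
  haps <- if (is.data.frame(H)) H$hap else as.character(H)
  n <- length(haps)
  if (n < 1) stop("H must contain at least one haplotype")
  if (n > 20) stop("refusing to enumerate clusters for ", n,
                   " haplotypes (2^n blowup); reduce the common set")
  out <- list()
  for (size in seq_len(n)) {
    sets <- utils::combn(n, size, simplify = FALSE)
    # combn emits index tuples in lexicographic order already
    out <- c(out, sets)
  }
  lapply(seq_along(out), function(k) {
    list(members = out[[k]], haps = haps[out[[k]]],
         label = sprintf("b%d_H%d", block_id, k))
  })
}

#' Cluster table for export
#'
#' @param HS cluster list from [enumerate_clusters()].
#' @param H common-haplotype data.frame with columns `hap`, `freq`.
#' @return data.frame: label, member haplotype strings (comma separated),
#'   summed frequency.
#' @export
cluster_table <- function(HS, H) {
  data.frame(label = vapply(HS, `[[`, character(1), "label"),
             haplotypes = vapply(HS, function(cl) paste(cl$haps, collapse = ","),
                                 character(1)),
             freq = vapply(HS, function(cl) sum(H$freq[cl$members]), numeric(1)),
             stringsAsFactors = FALSE)
}
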