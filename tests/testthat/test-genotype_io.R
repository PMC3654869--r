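test_that("PED/MAP parsing handles calls, missing pairs and malformed input", {
  map <- tempfile(fileext = ".map")
  ped <- tempfile(fileext = ".ped")
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200", "1\ts3\t0\t300"), map)
  writeLines(c("F1 S1 0 0 1 -9 A A G A C C",
               "F2 S2 0 0 2 -9 A A 0 0 C T",
               "F3 S3 0 0 1 -9 G A A 0 T T"), ped)
  g <- read_ped_map(ped, map)
  expect_identical(g$samples, c("S1", "S2", "S3"))
  expect_identical(unname(g$a1[1, ]), c("A", "A", "C"))
  expect_identical(unname(g$a2[1, ]), c("A", "G", "C"))
  # "0 0" pair and half-call both become fully missing
  expect_true(is.na(g$a1[2, 2]) && is.na(g$a2[2, 2]))
  expect_true(is.na(g$a1[3, 2]) && is.na(g$a2[3, 2]))

  writeLines("F1 S1 0 0 1 -9 A A G", ped)
  expect_error(read_ped_map(ped, map), "PED line 1")
  writeLines(c("F1 S1 0 0 1 -9 A A G A C C",
               "F2 S2 0 0 1 -9 T C G G C C"), ped)
  expect_error(read_ped_map(ped, map), "more than two alleles")
})

test_that("PED/MAP and phenotype round-trips are the identity", {
  cfg <- sim_config(seed = 7, n_samples = 25,
                    blocks = list(list(haps = c("AAC", "AAT", "AGC"),
                                       freqs = c(0.5, 0.3, 0.2))))
  sim <- simulate_cohort(cfg)
  # punch some missing calls through the writer as well
  sim$genotypes$a1[1, 2] <- sim$genotypes$a2[1, 2] <- NA_character_
  dir <- tempfile()
  paths <- write_cohort(sim, dir, trait_name = "HDL")
  g2 <- read_ped_map(paths["ped"], paths["map"])
  expect_identical(g2$samples, sim$genotypes$samples)
  expect_identical(g2$a1, sim$genotypes$a1)
  expect_identical(g2$a2, sim$genotypes$a2)
  expect_identical(g2$snps, sim$genotypes$snps)
  ph2 <- read_phenotypes(paths["pheno"], "HDL", c("area", "age", "sex", "bmi"))
  expect_identical(ph2$sample_id, sim$phenotypes$sample_id)
  expect_equal(ph2$trait, sim$phenotypes$trait, tolerance = 1e-12)
  expect_equal(ph2$bmi, sim$phenotypes$bmi, tolerance = 1e-12)
})

test_that("phenotype reader turns unparseable cells into missing and checks columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("iid\tHDL\tage\tsex\tbmi",
               "S1\t1.2\t40\t1\t24.4",
               "S2\tNA\t51\t0\t22.0",
               "S3\t0.9\t.\t1\t27.1"), f)
  ph <- read_phenotypes(f, "HDL", c("age", "sex", "bmi"))
  expect_equal(ph$trait, c(1.2, NA, 0.9))
  expect_equal(ph$age, c(40, 51, NA))
  expect_error(read_phenotypes(f, "LDL", "age"), "LDL")
})

test_that("QC filter drops low call rate, low MAF and HWE failures, idempotently", {
  set.seed(42)
  n <- 200
  # SNP 1: clean, HWE, MAF ~0.3; SNP 2: 6% missing; SNP 3: monomorphic;
  # SNP 4: gross HWE violation (every call heterozygous)
  d1 <- rbinom(n, 2, 0.3)
  mk <- function(d, a, b) list(a1 = ifelse(d == 2, a, ifelse(d == 1, a, b)),
                               a2 = ifelse(d == 2, a, b))
  s1 <- mk(d1, "A", "G")
  s2 <- mk(rbinom(n, 2, 0.4), "C", "T")
  miss <- seq_len(0.06 * n)
  s2$a1[miss] <- s2$a2[miss] <- NA
  s3 <- list(a1 = rep("A", n), a2 = rep("A", n))
  s4 <- list(a1 = rep("C", n), a2 = rep("G", n))
  snps <- data.frame(id = paste0("s", 1:4), chrom = "1", pos = c(1:4) * 1000L,
                     allele_a = c("A", "C", "A", "C"),
                     allele_b = c("G", "T", NA, "G"), stringsAsFactors = FALSE)
  g <- genotype_matrix(sprintf("S%03d", 1:n), snps,
                       cbind(s1$a1, s2$a1, s3$a1, s4$a1),
                       cbind(s1$a2, s2$a2, s3$a2, s4$a2))
  gf <- filter_snps(g)
  expect_identical(gf$snps$id, "s1")
  expect_identical(length(gf$samples), length(g$samples))
  gff <- filter_snps(gf)
  expect_identical(gff$snps, gf$snps)
  expect_identical(gff$a1, gf$a1)
  # relaxed thresholds keep the missingness-only SNP; order preserved
  g2 <- filter_snps(g, min_call = 0.90)
  expect_identical(g2$snps$id, c("s1", "s2"))
  expect_warning(filter_snps(g, min_maf = 0.9), "no SNPs pass")
})

test_that("HWE exact test agrees with a conditional multinomial oracle", {
  # oracle: enumerate genotype configurations with the observed allele count
  # and condition HWE multinomial probabilities on it
  oracle <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    q <- (2 * naa + nab) / (2 * n)
    probs <- c(q^2, 2 * q * (1 - q), (1 - q)^2)
    rare <- 2 * naa + nab
    hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
    joint <- vapply(hets, function(h) {
      aa <- (rare - h) / 2
      stats::dmultinom(c(aa, h, n - aa - h), prob = probs)
    }, numeric(1))
    joint <- joint / sum(joint)
    obs <- joint[hets == nab]
    sum(joint[joint <= obs * (1 + 1e-12)])
  }
  cases <- list(c(5, 25, 70), c(0, 0, 100), c(20, 20, 60), c(3, 4, 93),
                c(10, 50, 40), c(0, 100, 0), c(57, 14, 50))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
})

test_that("SNPs drawn at HWE survive the 1e-6 exact-test filter", {
  set.seed(99)
  p_ok <- replicate(300, {
    d <- rbinom(1000, 2, 0.25)
    hwe_exact_test(sum(d == 2), sum(d == 1), sum(d == 0)) >= 1e-6
  })
  expect_gte(mean(p_ok), 0.995)
})

test_that("VCF genotypes map to allele pairs with phase ignored", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "15\t1001\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1|1",
    "15\t1002\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0"), f)
  g <- read_vcf_genotypes(f)
  expect_identical(g$snps$id, c("rs1", "rs2"))
  expect_identical(unname(g$a1[, 1]), c("A", "A", "G"))
  expect_identical(unname(g$a2[, 1]), c("A", "G", "G"))
  expect_true(is.na(g$a1["S2", "rs2"]))
  expect_identical(unname(g$a2[, 2]), c("T", NA, "C"))
})
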