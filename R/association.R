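assoc_frame <- function(dose, trait, covariates) {
  df <- data.frame(trait = trait, dose = dose)
  if (!is.null(covariates) && length(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(dose))
    df <- cbind(df, covariates)
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

check_design <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("collinear design: coefficient(s) not estimable for ",
         paste(names(co)[is.na(co)], collapse = ", "))
}

#' Additive linear association of a 0/1/2 dose with a quantitative trait
#'
#' Ordinary least squares of the trait on the dose plus covariates and an
#' intercept; the p-value is a two-sided Wald t-test on the dose
#' coefficient. With `log_transform = TRUE` the protocol is dual: the
#' p-value comes from the fit on the log-transformed trait (normalising a
#' skewed concentration) while the reported effect and standard error come
#' from a second fit on the untransformed trait, so the effect stays in
#' trait units per minor dose. Samples missing the dose, trait or any
#' covariate are dropped listwise.
#'
#' @param dose integer 0/1/2 vector (NA allowed).
#' @param trait numeric trait vector, same length.
#' @param covariates optional data.frame of numeric covariates.
#' @param log_transform use the dual log-transform protocol (trait must be
#'   positive among complete cases).
#' @return list with `effect`, `stderr`, `p_value`, `n_used`.
#' @export
linear_assoc <- function(dose, trait, covariates = NULL, log_transform = FALSE) {
  df <- assoc_frame(dose, trait, covariates)
  if (nrow(df) < 10) stop("fewer than 10 complete cases")
  if (stats::var(df$dose) == 0) stop("collinear design: dose has no variation")
  fit_raw <- stats::lm(trait ~ ., data = df)
  check_design(fit_raw)
  sm_raw <- summary(fit_raw)$coefficients
  if (log_transform) {
    if (any(df$trait <= 0)) stop("log transform requires a positive trait")
    df_log <- df
    df_log$trait <- log(df$trait)
    fit_log <- stats::lm(trait ~ ., data = df_log)
    check_design(fit_log)
    p <- summary(fit_log)$coefficients["dose", 4]
  } else {
    p <- sm_raw["dose", 4]
  }
  list(effect = unname(sm_raw["dose", 1]), stderr = unname(sm_raw["dose", 2]),
       p_value = unname(p), n_used = nrow(df))
}

#' Additive logistic association of a 0/1/2 dose with a binary trait
#'
#' Maximum-likelihood logistic fit of the 0/1 outcome on the dose plus
#' covariates; the effect is the log-odds per minor dose with a Wald z
#' p-value. Complete separation (fitted probabilities collapsing to 0/1)
#' raises an error of class `dipclust_separation_error`.
#'
#' @inheritParams linear_assoc
#' @param trait binary 0/1 vector.
#' @return list with `effect`, `stderr`, `p_value`, `n_used`, `converged`.
#' @export
logistic_assoc <- function(dose, trait, covariates = NULL) {
  df <- assoc_frame(dose, trait, covariates)
  if (nrow(df) < 10) stop("fewer than 10 complete cases")
  if (!all(df$trait %in% c(0, 1))) stop("binary trait must contain only 0/1")
  if (length(unique(df$trait)) < 2) stop("both outcome classes must be present")
  if (stats::var(df$dose) == 0) stop("collinear design: dose has no variation")
  # dose-driven complete separation: case and control doses do not overlap
  if (min(df$dose[df$trait == 1]) > max(df$dose[df$trait == 0]) ||
      max(df$dose[df$trait == 1]) < min(df$dose[df$trait == 0]))
    stop(errorCondition("complete separation: dose perfectly predicts the outcome",
                        class = "dipclust_separation_error"))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(trait ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  check_design(fit)
  sm <- summary(fit)$coefficients
  if (sep_warn && abs(sm["dose", 1]) > 8)
    stop(errorCondition("complete separation: dose perfectly predicts the outcome",
                        class = "dipclust_separation_error"))
  list(effect = unname(sm["dose", 1]), stderr = unname(sm["dose", 2]),
       p_value = unname(sm["dose", 4]), n_used = nrow(df),
       converged = fit$converged && !sep_warn)
}

#' Single-SNP additive association
#'
#' The dose counts copies of the minor allele (the less frequent allele
#' among non-missing calls); genotype counts are reported as
#' (minor-homozygote, heterozygote, major-homozygote).
#'
#' @param g a [genotype_matrix()].
#' @param snp SNP index or id.
#' @param pheno phenotype data.frame aligned with `g` (see
#'   [align_samples()]).
#' @param covariate_names covariate columns of `pheno` to adjust for.
#' @param model "linear" or "logistic".
#' @param log_transform passed to [linear_assoc()].
#' @return one-row data.frame: `test_id`, `minor`, `major`,
#'   `n_minor_homo`, `n_het`, `n_major_homo`, `effect`, `stderr`,
#'   `p_value`, `n_used`.
#' @export
single_snp_assoc <- function(g, snp, pheno, covariate_names = character(),
                             model = c("linear", "logistic"),
                             log_transform = FALSE) {
  model <- match.arg(model)
  k <- if (is.character(snp)) match(snp, g$snps$id) else snp
  if (is.na(k)) stop("unknown SNP: ", snp)
  stopifnot(identical(g$samples, pheno$sample_id))
  a <- g$snps$allele_a[k]; b <- g$snps$allele_b[k]
  dose_a <- (g$a1[, k] == a) + (g$a2[, k] == a)
  fa <- mean(dose_a, na.rm = TRUE) / 2
  if (is.na(b) || fa <= 0.5) {
    minor <- a; major <- b; dose <- dose_a
  } else {
    minor <- b; major <- a; dose <- 2 - dose_a
  }
  counts <- c(sum(dose == 2, na.rm = TRUE), sum(dose == 1, na.rm = TRUE),
              sum(dose == 0, na.rm = TRUE))
  cov <- if (length(covariate_names)) pheno[, covariate_names, drop = FALSE] else NULL
  res <- if (model == "linear")
    linear_assoc(dose, pheno$trait, cov, log_transform)
  else logistic_assoc(dose, pheno$trait, cov)
  data.frame(test_id = g$snps$id[k], minor = minor,
             major = ifelse(is.na(major), "-", major),
             n_minor_homo = counts[1], n_het = counts[2], n_major_homo = counts[3],
             effect = res$effect, stderr = res$stderr, p_value = res$p_value,
             n_used = res$n_used, stringsAsFactors = FALSE)
}

#' Association test of one diplotype pattern
#'
#' Codes the phased samples under the pattern, orients the dose to the
#' minor cluster and regresses the trait on it with covariates.
#'
#' @param pattern one pattern from [enumerate_patterns()].
#' @param diplos phased samples from [phase_samples()].
#' @param H common-haplotype data.frame the pattern refers to.
#' @param pheno phenotype data.frame keyed by `sample_id`.
#' @inheritParams single_snp_assoc
#' @return one-row data.frame in the [single_snp_assoc()] layout, with
#'   `minor`/`major` holding cluster labels.
#' @export
diplotype_assoc <- function(pattern, diplos, H, pheno,
                            covariate_names = character(),
                            model = c("linear", "logistic"),
                            log_transform = FALSE) {
  model <- match.arg(model)
  coded <- code_samples(pattern, diplos, H)
  ori <- assign_minor_major(pattern, coded)
  ph <- pheno[match(coded$sample_id, pheno$sample_id), , drop = FALSE]
  cov <- if (length(covariate_names)) ph[, covariate_names, drop = FALSE] else NULL
  res <- if (model == "linear")
    linear_assoc(ori$dose, ph$trait, cov, log_transform)
  else logistic_assoc(ori$dose, ph$trait, cov)
  data.frame(test_id = pattern$id, minor = ori$minor_label,
             major = ori$major_label,
             n_minor_homo = ori$counts[1], n_het = ori$counts[2],
             n_major_homo = ori$counts[3],
             effect = res$effect, stderr = res$stderr, p_value = res$p_value,
             n_used = res$n_used, stringsAsFactors = FALSE)
}

#' Bonferroni annotation over the full test family
#'
#' The per-test threshold is `alpha` divided by the total number of tests
#' (single-SNP plus diplotype patterns across all blocks); each result is
#' flagged significant when its p-value is below that threshold.
#'
#' @param results data.frame of stacked association rows.
#' @param alpha family-wise level (default 0.05).
#' @return `results` with added columns `p_threshold` and `significant`.
#' @export
bonferroni <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) stop("no association results")
  thr <- alpha / nrow(results)
  results$p_threshold <- thr
  results$significant <- results$p_value < thr
  results
}

#' Write association results as TSV
#'
#' Mirrors the tabular report convention: test id, "minor; major" labels,
#' counts triplet `a/b/c`, effect, SE, p (scientific, 3 significant
#' digits), significance flag.
#'
#' @param results annotated data.frame from [bonferroni()].
#' @param path output path.
#' @export
write_assoc_tsv <- function(results, path) {
  if (nrow(results) == 0) {
    out <- data.frame(test = character(), minor_major = character(),
                      counts = character(), effect = numeric(),
                      stderr = numeric(), p_value = character(),
                      significant = logical())
    utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
    return(invisible(out))
  }
  out <- data.frame(
    test = results$test_id,
    minor_major = paste0(results$minor, "; ", results$major),
    counts = paste(results$n_minor_homo, results$n_het, results$n_major_homo,
                   sep = "/"),
    effect = signif(results$effect, 4),
    stderr = signif(results$stderr, 4),
    p_value = formatC(results$p_value, format = "e", digits = 2),
    significant = results$significant,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(out)
}
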