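#' Partition discovery pairs into attempted / not attempted
#'
#' Replication of a pair is not attempted when its CpG probe failed quality
#' control in the replication set or when the SNP's imputation quality is
#' below `r2_min` (strict `<`). Pairs with no quality entry are conservatively
#' not attempted (reason `"unknown quality"`, logged with a message).
#'
#' @param pairs data.frame with `pair_id`, `snp_id`, `cpg_id`.
#' @param probe_qc data.frame `cpg_id`, `pass` (logical).
#' @param imputation_quality data.frame `snp_id`, `r2` (genotyped SNPs may
#'   use `r2 = 1`).
#' @param r2_min Imputation-quality threshold (default 0.3).
#' @return `pairs` with added columns `attempted` (logical) and `reason`.
#' @export
attempted_filter <- function(pairs, probe_qc, imputation_quality,
                             r2_min = 0.3) {
  pass <- probe_qc$pass[match(pairs$cpg_id, probe_qc$cpg_id)]
  r2 <- imputation_quality$r2[match(pairs$snp_id, imputation_quality$snp_id)]
  reason <- rep(NA_character_, nrow(pairs))
  unknown <- is.na(pass) | is.na(r2)
  reason[is.na(r2) | (!is.na(r2) & r2 < r2_min)] <- "imputation_quality"
  reason[is.na(pass) | (!is.na(pass) & !pass)] <- "probe_qc"
  reason[unknown] <- "unknown quality"
  if (any(unknown))
    message(sum(unknown), " pair(s) with no quality entry: not attempted")
  attempted <- !unknown & pass & r2 >= r2_min
  pairs$attempted <- attempted
  pairs$reason <- ifelse(attempted, NA_character_, reason)
  pairs
}

#' Test one discovery pair in a replication cohort
#'
#' Covariate-adjusted linear model of the methylation outcome (raw beta or
#' its logit) on the genotype or imputed allele dosage. Significance comes
#' from a likelihood-ratio test (`n * ln(RSS0/RSS1)` vs chi-squared, 1 df)
#' or a Wald test (squared coefficient z-score vs chi-squared, 1 df). The
#' effect sign is recorded for direction-consistency checks against the
#' discovery cohort.
#'
#' @param y Beta values at the CpG in the replication cohort.
#' @param g Genotype codes or continuous allele dosage.
#' @param X Covariate data.frame or `NULL`.
#' @param outcome `"raw"` (beta as is) or `"logit"`.
#' @param test `"lrt"` or `"wald"`.
#' @return One-row data.frame: `model`, `test`, `n`, `p`, `beta_hat`,
#'   `sign`.
#' @export
replicate_pair <- function(y, g, X = NULL, outcome = c("raw", "logit"),
                           test = c("lrt", "wald")) {
  outcome <- match.arg(outcome)
  test <- match.arg(test)
  ok <- !is.na(y) & !is.na(g)
  if (!is.null(X)) ok <- ok & stats::complete.cases(X)
  y <- y[ok]; g <- as.numeric(g[ok])
  if (outcome == "logit") {
    if (any(y <= 0 | y >= 1)) stop("logit outcome needs beta in (0,1)")
    y <- logit(y)
  }
  if (stats::var(y) == 0) stop("zero-variance outcome")
  if (stats::var(g) == 0) stop("degenerate predictor")
  n <- length(y)
  mm <- build_design(if (is.null(X)) NULL else X[ok, , drop = FALSE], n)
  f1 <- stats::lm.fit(cbind(mm, g = g), y)
  b <- unname(f1$coefficients["g"])
  if (test == "lrt") {
    f0 <- stats::lm.fit(mm, y)
    lrt <- n * log(sum(f0$residuals^2) /
                     max(sum(f1$residuals^2), .Machine$double.xmin))
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    rss1 <- sum(f1$residuals^2)
    df <- n - f1$rank
    R <- chol2inv(f1$qr$qr[seq_len(f1$rank), seq_len(f1$rank), drop = FALSE])
    se <- sqrt(rss1 / df * R[f1$rank, f1$rank])
    p <- stats::pchisq((b / se)^2, df = 1, lower.tail = FALSE)
  }
  data.frame(model = outcome, test = test, n = n, p = p, beta_hat = b,
             sign = sign(b))
}

#' Replicate a set of discovery pairs in one cohort
#'
#' Runs [attempted_filter()] then [replicate_pair()] for every attempted
#' pair, recording direction consistency against the discovery effect signs
#' when supplied.
#'
#' @param pairs data.frame `pair_id`, `snp_id`, `cpg_id`, optional
#'   `discovery_sign`.
#' @param beta Sample x CpG beta matrix of the replication cohort.
#' @param genotypes Sample x SNP matrix of codes or dosages.
#' @param X Covariate data.frame or `NULL`.
#' @param probe_qc,imputation_quality,r2_min Passed to [attempted_filter()].
#' @param outcome,test Passed to [replicate_pair()].
#' @param set Label for this replication set.
#' @return data.frame of replication records: one row per pair with
#'   `pair_id`, `set`, `attempted`, `reason`, `p`, `sign`,
#'   `direction_consistent`.
#' @export
replicate_set <- function(pairs, beta, genotypes, X = NULL,
                          probe_qc = NULL, imputation_quality = NULL,
                          r2_min = 0.3, outcome = c("raw", "logit"),
                          test = c("lrt", "wald"), set = "replication") {
  if (is.null(probe_qc))
    probe_qc <- data.frame(cpg_id = colnames(beta), pass = TRUE)
  if (is.null(imputation_quality))
    imputation_quality <- data.frame(snp_id = colnames(genotypes), r2 = 1)
  pr <- attempted_filter(pairs, probe_qc, imputation_quality, r2_min)
  pr$set <- set
  pr$p <- NA_real_
  pr$sign <- NA_real_
  for (i in which(pr$attempted)) {
    rec <- tryCatch(
      replicate_pair(beta[, pr$cpg_id[i]], genotypes[, pr$snp_id[i]], X,
                     outcome = outcome, test = test),
      error = function(e) NULL)
    if (is.null(rec)) {
      pr$attempted[i] <- FALSE
      pr$reason[i] <- "degenerate model"
      next
    }
    pr$p[i] <- rec$p
    pr$sign[i] <- rec$sign
  }
  pr$direction_consistent <- if (!is.null(pr$discovery_sign))
    pr$sign == pr$discovery_sign else NA
  pr
}

#' Harmonize allele coding between two cohorts
#'
#' Aligns the counted allele of a replication `genotype_matrix` with a
#' reference cohort by SNP id: where the counted alleles differ, codes are
#' flipped (`2 - g`). Strand-ambiguous SNPs (A/T or C/G) cannot be resolved
#' by allele matching alone and are flagged.
#'
#' @param G Replication `genotype_matrix` whose `info` carries a
#'   `counted_allele` column.
#' @param ref_info Reference cohort `info` data.frame (`snp_id`,
#'   `counted_allele`, `ref`, `alt`).
#' @return `G` with aligned codes; `info` gains a logical `ambiguous`
#'   column.
#' @export
harmonize_alleles <- function(G, ref_info) {
  i <- match(G$info$snp_id, ref_info$snp_id)
  flip <- !is.na(i) & G$info$counted_allele != ref_info$counted_allele[i]
  G$codes[, flip] <- 2L - G$codes[, flip]
  G$info$counted_allele[flip] <- ref_info$counted_allele[i][flip]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  G$info$ambiguous <- G$info$alt == comp[G$info$ref]
  G
}

#' Replication-rate accounting
#'
#' A pair is replicated when it is significant at BH FDR `q` within the
#' attempted set of at least one replication cohort. The overall rate
#' divides by all discovery pairs; the among-attempted rate ignores pairs
#' whose replication was not attempted in any cohort.
#'
#' @param records Replication records (rows from one or more
#'   [replicate_set()] calls, distinguished by their `set` column), or a
#'   precomputed data.frame with `pair_id`, `set`, `attempted`, `p`.
#' @param discovery_total Number of discovery pairs.
#' @param q FDR level within each attempted set (default 0.05).
#' @return List: `overall`, `among_attempted`, `replicated`,
#'   `not_attempted`, `per_set` (data.frame), `replicated_pairs`.
#' @export
replication_rates <- function(records, discovery_total, q = 0.05) {
  pair_ids <- unique(records$pair_id)
  if (discovery_total < length(pair_ids))
    stop("discovery_total smaller than the number of distinct pairs")
  if (!any(records$attempted)) stop("zero attempted pairs")
  rep_pairs <- character()
  per_set <- list()
  for (s in unique(records$set)) {
    rs <- records[records$set == s & records$attempted, , drop = FALSE]
    if (nrow(rs) == 0L) next
    f <- bh_fdr(rs$p, q = q)
    rep_pairs <- union(rep_pairs, rs$pair_id[f$significant])
    per_set[[s]] <- data.frame(set = s, attempted = nrow(rs),
                               replicated = f$n_significant,
                               stringsAsFactors = FALSE)
  }
  att <- tapply(records$attempted, records$pair_id, any)
  not_attempted <- sum(!att)
  # pairs in the discovery list but absent from the records were never tried
  not_attempted <- not_attempted + (discovery_total - length(pair_ids))
  replicated <- length(rep_pairs)
  list(overall = replicated / discovery_total,
       among_attempted = replicated / (discovery_total - not_attempted),
       replicated = replicated, not_attempted = not_attempted,
       per_set = do.call(rbind, per_set), replicated_pairs = rep_pairs)
}

#' QQ diagnostic and genomic inflation factor
#'
#' Converts p-values to 1-df chi-squared quantiles and reports the
#' inflation factor lambda: the ratio of the observed median to the
#' expected median (0.4549) of the chi-squared statistic, approximately 1
#' under the null. Also returns sorted observed and expected `-log10(p)`
#' quantiles with a 95% band from the order-statistic Beta(i, n - i + 1)
#' distribution, ready for a QQ plot.
#'
#' @param p Vector of p-values in (0, 1\]; at least 10.
#' @return Object of class `qq_diagnostic`: `lambda`, `n`, and sorted
#'   vectors `expected`, `observed`, `band_lower`, `band_upper`
#'   (all -log10 scale).
#' @export
qq_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 10L) stop("need at least 10 p-values")
  if (any(p <= 0) || any(p > 1)) stop("p-values must be in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  n <- length(p)
  i <- seq_len(n)
  structure(list(
    lambda = lambda, n = n,
    expected = -log10(i / (n + 1)),
    observed = -log10(sort(p)),
    band_lower = -log10(stats::qbeta(0.975, i, n - i + 1)),
    band_upper = -log10(stats::qbeta(0.025, i, n - i + 1))),
    class = "qq_diagnostic")
}

#' @export
print.qq_diagnostic <- function(x, ...) {
  cat(sprintf("qq_diagnostic: n = %d, lambda = %.3f\n", x$n, x$lambda))
  invisible(x)
}
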