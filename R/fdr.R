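#' Benjamini-Hochberg step-up with known test count
#'
#' Finds the largest p-value cutoff `p* = max{ p(i) : p(i) <= i * q / m }`
#' and the significant set `{p <= p*}`. `m` may exceed the number of
#' supplied p-values when the caller streamed only the small-p tail of a
#' larger scan (see [meqtl_scan()]'s `p_cap`): the result is identical to
#' running BH on all `m` p-values whenever `p*` falls inside the retained
#' tail, because the retained values are exactly the `length(p)` smallest
#' and therefore hold the global ranks `1..length(p)`.
#'
#' @param p Numeric vector of p-values.
#' @param m Total number of tests (default `length(p)`).
#' @param q Target false discovery rate (default 0.05).
#' @return Object of class `fdr_result`: `q`, `m`, `p_star` (NA when
#'   nothing is significant), `significant` (logical, aligned with `p`),
#'   `n_significant`.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.2, 0.9), q = 0.05)
#' @export
bh_fdr <- function(p, m = length(p), q = 0.05) {
  if (m == 0L) stop("m must be positive")
  if (m < length(p)) stop("m is smaller than the number of p-values")
  sp <- sort(p)
  ok <- which(sp <= q * seq_along(sp) / m)
  if (length(ok) == 0L) {
    p_star <- NA_real_
    sig <- rep(FALSE, length(p))
  } else {
    p_star <- sp[max(ok)]
    sig <- p <= p_star
  }
  structure(list(q = q, m = m, p_star = p_star, significant = sig,
                 n_significant = sum(sig)), class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("fdr_result: %d of m = %s tests significant at q = %g (p* = %s)\n",
              x$n_significant, format(x$m, big.mark = ","), x$q,
              format(x$p_star)))
  invisible(x)
}

#' FDR control per distance class of a scan
#'
#' Applies [bh_fdr()] separately within the proximal or the distal class of
#' a [meqtl_scan()] result, using the exact candidate count of that class as
#' `m`. Warns when the cutoff is not safely below the scan's `p_cap` (in
#' which case the streamed tail may have truncated the significant set).
#'
#' @param scan A `meqtl_scan` object.
#' @param class `"distal"` (both distal classes pooled) or `"proximal"`.
#' @param q Target FDR.
#' @return List: `records` (significant records, ordered by p), `fdr` (the
#'   `fdr_result`), `class`.
#' @export
scan_fdr <- function(scan, class = c("distal", "proximal"), q = 0.05) {
  class <- match.arg(class)
  classes <- if (class == "proximal") "proximal" else
    c("distal_same_chrom", "distal_inter_chrom")
  rec <- scan$records[scan$records$class %in% classes, , drop = FALSE]
  m <- sum(scan$counts[classes])
  f <- bh_fdr(rec$p, m = m, q = q)
  if (!is.na(f$p_star) && scan$p_cap < 1 && f$p_star >= scan$p_cap)
    warning("BH cutoff reached the scan's p_cap; rerun with a larger p_cap")
  sig <- rec[f$significant, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  rownames(sig) <- NULL
  list(records = sig, fdr = f, class = class)
}

#' Stratified summary of significant CpG sites
#'
#' Counts significant CpG sites in a variability-quintile by effect-size-bin
#' table. Each CpG is counted once, at its best (largest partial R2) record.
#' Records with R2 below the lowest bin edge land in an extra `"<2%"` bin
#' and are logged with a message.
#'
#' @param records Significant association records (from [scan_fdr()]).
#' @param variability A [variability_profile()] covering every CpG in
#'   `records`.
#' @param r2_breaks Lower bin edges on the R2 scale
#'   (default 2/5/10/25/50/75%).
#' @return List: `table` (quintile x bin counts), `best` (the per-CpG best
#'   records with their bin and quintile), `total` (number of sites).
#' @export
summarize_counts <- function(records, variability,
                             r2_breaks = c(0.02, 0.05, 0.10, 0.25,
                                           0.50, 0.75)) {
  if (nrow(records) == 0L)
    stop("no records to summarize")
  best <- records[order(records$cpg_id, -records$r2), , drop = FALSE]
  best <- best[!duplicated(best$cpg_id), , drop = FALSE]
  qx <- variability$quintile[match(best$cpg_id, variability$cpg_id)]
  if (anyNA(qx)) stop("record CpG missing from the variability profile")
  labs <- c("<2%",
            paste0(r2_breaks[-length(r2_breaks)] * 100, "-",
                   r2_breaks[-1L] * 100, "%"),
            paste0(r2_breaks[length(r2_breaks)] * 100, "%+"))
  bin <- cut(best$r2, breaks = c(-Inf, r2_breaks, Inf), labels = labs,
             right = FALSE)
  if (any(bin == "<2%"))
    message(sum(bin == "<2%"), " site(s) below the lowest R2 bin")
  best$r2_bin <- bin
  best$quintile <- qx
  tab <- table(quintile = qx, r2_bin = bin)
  list(table = tab, best = best, total = nrow(best))
}

#' Overlap of significant sets between strata
#'
#' Proportion of shared significant pairs between two analyses (e.g. cases
#' and controls analyzed separately), relative to the smaller set:
#' `|A intersect B| / min(|A|, |B|)`.
#'
#' @param sig_a,sig_b Character vectors of significant pair ids (e.g.
#'   `paste(snp_id, cpg_id)`).
#' @return Overlap proportion in \[0,1\].
#' @export
stratum_concordance <- function(sig_a, sig_b) {
  if (length(sig_a) == 0L && length(sig_b) == 0L)
    stop("both significant sets are empty")
  if (length(sig_a) == 0L || length(sig_b) == 0L) return(0)
  length(intersect(sig_a, sig_b)) / min(length(sig_a), length(sig_b))
}

#' Case-control confounding check at significant sites
#'
#' Tests, for each CpG, whether methylation differs between cases and
#' controls after adjusting for the remaining covariates, and reports the
#' fraction of sites significant at BH FDR `q`. A fraction near the nominal
#' level indicates the phenotype is not a systematic confounder of the
#' meQTL catalogue.
#'
#' @param beta Sample x CpG beta matrix restricted to the sites of interest.
#' @param status Binary phenotype vector (factor/character/0-1).
#' @param X Covariate data.frame excluding the status column, or `NULL`.
#' @param q FDR level.
#' @return List: `p` (per-site p-values), `fdr` (`fdr_result`),
#'   `n_significant`, `fraction`.
#' @export
phenotype_confound_check <- function(beta, status, X = NULL, q = 0.05) {
  s <- as.integer(as.factor(status)) - 1L
  if (length(unique(s[!is.na(s)])) != 2L)
    stop("status must have exactly two classes")
  p <- vapply(seq_len(ncol(beta)),
              function(j) fit_pair(beta[, j], s, X)$p, 0)
  names(p) <- colnames(beta)
  f <- bh_fdr(p, q = q)
  list(p = p, fdr = f, n_significant = f$n_significant,
       fraction = f$n_significant / length(p))
}
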