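#' Methylation beta-value from intensity signals
#'
#' `compute_beta()` uses the floored ratio
#' `beta = max(M, 1) / (max(M, 1) + max(U, 1))`: flooring both signals at 1
#' keeps the ratio strictly inside (0,1) and yields a continuous distribution
#' that does not bias against a fully methylated state. (The formula is often
#' printed with "min"; read literally that would cap every real intensity at
#' 1 and force beta = 0.5 everywhere, so the floor is the only reading
#' consistent with its stated rationale.)
#'
#' `compute_beta_legacy()` is the classical platform definition
#' `beta = max(M, 0) / (max(M, 0) + max(U, 0) + 100)`: the offset keeps beta
#' away from 1 and a zero numerator is possible, producing a point mass at 0
#' (the behaviour the floored formula avoids).
#'
#' Both are vectorized and preserve matrix dimensions.
#'
#' @param M,U Methylated / unmethylated intensity signals (non-negative,
#'   possibly background-corrected); same shape.
#' @return Beta values, same shape as the inputs. `compute_beta()` is always
#'   in (0,1); the legacy form is in \[0,1).
#' @examples
#' compute_beta(600, 200)         # 0.75
#' compute_beta(0, 0)             # 0.5 (both floored to 1)
#' compute_beta_legacy(600, 200)  # 600/900
#' @export
compute_beta <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  fM <- pmax(M, 1)
  fU <- pmax(U, 1)
  fM / (fM + fU)
}

#' @rdname compute_beta
#' @export
compute_beta_legacy <- function(M, U) {
  fM <- pmax(M, 0)
  fU <- pmax(U, 0)
  fM / (fM + fU + 100)
}

#' Mask beta values that fail detection
#'
#' Sets to missing every beta value whose detection score indicates the
#' total signal cannot be distinguished from background. Two conventions are
#' supported: under `"confidence"` the score is the probability that signal
#' is distinguishable from background (low = bad), so entries with
#' `score < threshold` are masked; under `"illumina_p"` the score is a
#' detection p-value in the usual export convention (high = bad), so entries
#' with `score > threshold` are masked.
#'
#' @param beta Sample x CpG beta matrix.
#' @param detection Matching matrix of detection scores in \[0,1\].
#' @param threshold Masking threshold (default 0.01, i.e. 1%).
#' @param convention `"confidence"` (default) or `"illumina_p"`.
#' @return `beta` with failing entries set to `NA`.
#' @export
mask_detection <- function(beta, detection, threshold = 0.01,
                           convention = c("confidence", "illumina_p")) {
  convention <- match.arg(convention)
  if (!all(dim(beta) == dim(detection)))
    stop("beta and detection shapes differ")
  if (threshold < 0 || threshold > 1)
    stop("threshold outside [0, 1]")
  bad <- if (convention == "confidence") detection < threshold
         else detection > threshold
  beta[bad] <- NA_real_
  beta
}

#' Discard probes with excess missingness
#'
#' A probe is discarded when, after sample exclusion and detection masking,
#' its fraction of missing values is strictly greater than `max_missing`.
#'
#' @param beta Sample x CpG beta matrix with `NA` for masked values.
#' @param max_missing Maximum tolerated missing fraction (default 0.01).
#' @return List with character vectors `kept` and `discarded` (CpG ids) and
#'   the per-probe missing fraction `missing_fraction`.
#' @export
filter_probe_missingness <- function(beta, max_missing = 0.01) {
  if (length(beta) == 0L) stop("empty beta matrix")
  frac <- colMeans(is.na(beta))
  ids <- colnames(beta)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(beta)))
  list(kept = ids[frac <= max_missing],
       discarded = ids[frac > max_missing],
       missing_fraction = stats::setNames(frac, ids))
}

#' Flag probes compromised by polymorphisms
#'
#' Applies the polymorphic-probe exclusion rules: a SNP at the CpG cytosine
#' or guanine base flags the probe regardless of allele frequency
#' (`polymorphic_target`); for Infinium I probes a SNP at the single-base
#' extension position (the base before the CpG cytosine) also flags it
#' regardless of frequency; a SNP elsewhere in the probe target sequence
#' flags the probe only when its MAF exceeds `body_maf_threshold`
#' (`polymorphic_body`).
#'
#' Probe geometry is taken as plus-strand: the cytosine at `pos`, the guanine
#' at `pos + 1`, single-base extension at `pos - 1`.
#'
#' @param cpg_annot data.frame with `cpg_id`, `chrom`, `pos` (CpG cytosine,
#'   1-based), `probe_type` ("I"/"II"), `probe_start`, `probe_end` (target
#'   interval, 1-based inclusive).
#' @param snp_table data.frame with `chrom`, `pos` (1-based), `maf`.
#' @param body_maf_threshold MAF above which a probe-body SNP flags the probe
#'   (strictly greater; default 0.05).
#' @return data.frame `cpg_id`, `status` in
#'   `{kept, polymorphic_target, polymorphic_body}`.
#' @export
flag_polymorphic_probes <- function(cpg_annot, snp_table,
                                    body_maf_threshold = 0.05) {
  need <- c("cpg_id", "chrom", "pos", "probe_type", "probe_start", "probe_end")
  if (!all(need %in% names(cpg_annot)))
    stop("probe interval or geometry missing from cpg_annot")
  status <- rep("kept", nrow(cpg_annot))
  for (i in seq_len(nrow(cpg_annot))) {
    a <- cpg_annot[i, ]
    s <- snp_table[snp_table$chrom == a$chrom, , drop = FALSE]
    if (nrow(s) == 0L) next
    target_pos <- c(a$pos, a$pos + 1L,
                    if (a$probe_type == "I") a$pos - 1L)
    if (any(s$pos %in% target_pos)) {
      status[i] <- "polymorphic_target"
    } else {
      body <- s$pos >= a$probe_start & s$pos <= a$probe_end &
        s$maf > body_maf_threshold
      if (any(body)) status[i] <- "polymorphic_body"
    }
  }
  data.frame(cpg_id = cpg_annot$cpg_id, status = status,
             stringsAsFactors = FALSE)
}

#' Probe filter report
#'
#' Combines all probe-level exclusion rules into one exhaustive, exclusive
#' status per probe, with fixed priority
#' `polymorphic_target > polymorphic_body > cross_reactive > missingness >
#' kept` (the priority affects only how a multiply-flagged probe is counted,
#' not the kept set).
#'
#' @param beta Sample x CpG beta matrix (after detection masking and sample
#'   exclusion).
#' @param cpg_annot,snp_table,body_maf_threshold Passed to
#'   [flag_polymorphic_probes()]; `cpg_annot` may be `NULL` to skip the rule.
#' @param cross_reactive Character vector of blacklisted probe ids (consumed
#'   as an input list; the sequence-identity screen that produces it is not
#'   recomputed here).
#' @param max_missing Passed to [filter_probe_missingness()].
#' @return Object of class `probe_filter_report`: list with `status`
#'   (data.frame `cpg_id`, `status`), `counts` (named integer vector over all
#'   categories, summing to the number of probes) and `kept` ids.
#' @export
probe_filter_report <- function(beta, cpg_annot = NULL, snp_table = NULL,
                                cross_reactive = character(),
                                max_missing = 0.01,
                                body_maf_threshold = 0.05) {
  ids <- colnames(beta)
  status <- rep("kept", length(ids))
  miss <- filter_probe_missingness(beta, max_missing)
  status[ids %in% miss$discarded] <- "missingness"
  status[ids %in% cross_reactive] <- "cross_reactive"
  if (!is.null(cpg_annot)) {
    pf <- flag_polymorphic_probes(cpg_annot, snp_table, body_maf_threshold)
    status[match(pf$cpg_id[pf$status == "polymorphic_body"], ids)] <-
      "polymorphic_body"
    status[match(pf$cpg_id[pf$status == "polymorphic_target"], ids)] <-
      "polymorphic_target"
  }
  lev <- c("kept", "missingness", "polymorphic_target", "polymorphic_body",
           "cross_reactive")
  counts <- table(factor(status, levels = lev))
  structure(list(status = data.frame(cpg_id = ids, status = status,
                                     stringsAsFactors = FALSE),
                 counts = c(counts), kept = ids[status == "kept"]),
            class = "probe_filter_report")
}

#' @export
print.probe_filter_report <- function(x, ...) {
  cat("probe_filter_report:\n")
  print(x$counts)
  invisible(x)
}

#' Interquartile-range outlier rule
#'
#' Flags any value lying strictly more than `k` interquartile ranges away
#' from the closest quartile: `x > Q3 + k * IQR` or `x < Q1 - k * IQR`.
#' Quartiles use the linear-interpolation percentile definition
#' (`stats::quantile` type 7). Used for sample exclusion on internal-control
#' summaries and on principal-component score vectors.
#'
#' @param values Named numeric vector (one value per sample); at least 4.
#' @param k IQR multiplier (default 3).
#' @return Names (or indices) of the flagged outliers.
#' @export
iqr_outliers <- function(values, k = 3) {
  idx <- which(!is.na(values))
  if (length(idx) < 4L) stop("need at least 4 values")
  x <- values[idx]
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  bad <- idx[x > q[2L] + k * iqr | x < q[1L] - k * iqr]
  if (is.null(names(values))) bad else names(values)[bad]
}

#' Resolve duplicate samples by detection failures
#'
#' For each group of replicate measurements of the same donor, keeps the one
#' with the smallest number of sites failing detection; ties are broken by
#' lexicographic sample id.
#'
#' @param groups List of character vectors of sample ids (one per duplicate
#'   group).
#' @param failure_counts Named integer vector: per-sample count of sites with
#'   failing detection scores (computed under the chosen detection
#'   convention).
#' @return Character vector: the retained sample id per group.
#' @export
resolve_duplicates <- function(groups, failure_counts) {
  vapply(groups, function(g) {
    if (length(g) == 0L) stop("empty duplicate group")
    cnt <- failure_counts[g]
    if (any(is.na(cnt))) stop("missing failure count for a group member")
    g <- sort(g)                     # lexicographic tie-break
    g[which.min(cnt[g])]
  }, "")
}

#' Sample-level quality control
#'
#' Applies the IQR outlier rule to each supplied per-sample metric vector
#' (internal-control summaries and/or PC score vectors) and returns the union
#' of flagged samples.
#'
#' @param metrics Named list of per-sample numeric vectors (all named by
#'   sample id).
#' @param k IQR multiplier passed to [iqr_outliers()].
#' @return List with `excluded` (unique flagged sample ids) and `by_metric`.
#' @export
sample_qc <- function(metrics, k = 3) {
  by_metric <- lapply(metrics, iqr_outliers, k = k)
  list(excluded = sort(unique(unlist(by_metric))), by_metric = by_metric)
}
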