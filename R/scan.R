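#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact p-value for departure from Hardy-Weinberg proportions given observed
#' genotype counts, computed by full enumeration of heterozygote counts
#' conditional on the allele counts (summing the probabilities of all
#' configurations no more probable than the observed one). A chi-squared
#' (1 df) alternative is available.
#'
#' @param n0,n1,n2 Counts of the three genotype classes (major homozygote,
#'   heterozygote, minor homozygote; orientation does not matter).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return Two-sided p-value (1 for monomorphic SNPs).
#' @export
hwe_exact_test <- function(n0, n1, n2, method = c("exact", "chisq")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  if (n == 0L) return(NA_real_)
  nA <- 2L * n0 + n1
  nB <- 2L * n2 + n1
  if (nA == 0L || nB == 0L) return(1)
  if (method == "chisq") {
    p <- nA / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # valid heterozygote counts share the parity of the rarer allele count
  nr <- min(nA, nB)
  h <- seq(nr %% 2L, nr, by = 2L)
  logp <- h * log(2) + lgamma(n + 1) - lgamma((nA - h) / 2 + 1) -
    lgamma(h + 1) - lgamma((nB - h) / 2 + 1) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n1, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Drops SNPs with minor allele frequency below `maf_min` in any sample
#' stratum (e.g. cases or controls), genotype frequencies inconsistent with
#' Hardy-Weinberg equilibrium at `hwe_alpha` computed on all samples, or
#' call rate below `call_rate_min`.
#'
#' @param G A `genotype_matrix`.
#' @param strata Optional factor/character vector over samples (e.g.
#'   case/control); MAF is checked within every stratum. `NULL` = one
#'   stratum.
#' @param maf_min,hwe_alpha,call_rate_min Thresholds (strict `<` drops).
#' @param hwe_test Passed to [hwe_exact_test()].
#' @return List: `kept` (SNP ids), `report` (per-SNP data.frame with
#'   thresholds and status), `genotypes` (the filtered `genotype_matrix`).
#' @export
genotype_qc <- function(G, strata = NULL, maf_min = 0.05, hwe_alpha = 1e-4,
                        call_rate_min = 0.90,
                        hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  codes <- G$codes
  n <- nrow(codes)
  if (is.null(strata)) strata <- rep("all", n)
  strata <- as.factor(strata)
  if (length(strata) != n) stop("strata labels must cover all samples")
  if (any(tabulate(strata) == 0L)) stop("empty stratum")

  maf_by <- sapply(levels(strata), function(s) {
    f <- colMeans(codes[strata == s, , drop = FALSE], na.rm = TRUE) / 2
    pmin(f, 1 - f)
  })
  maf_by <- matrix(maf_by, ncol = nlevels(strata),
                   dimnames = list(colnames(codes), levels(strata)))
  min_maf <- apply(maf_by, 1L, min)
  call_rate <- colMeans(!is.na(codes))
  hwe_p <- apply(codes, 2L, function(g) {
    cnt <- tabulate(g + 1L, nbins = 3L)
    hwe_exact_test(cnt[1L], cnt[2L], cnt[3L], method = hwe_test)
  })
  status <- rep("kept", ncol(codes))
  status[hwe_p < hwe_alpha] <- "hwe"
  status[call_rate < call_rate_min] <- "call_rate"
  status[min_maf < maf_min] <- "maf"
  report <- data.frame(snp_id = colnames(codes), maf_by, call_rate,
                       hwe_p, status, stringsAsFactors = FALSE,
                       check.names = FALSE)
  rownames(report) <- NULL
  kept <- report$snp_id[status == "kept"]
  Gk <- structure(list(codes = codes[, kept, drop = FALSE],
                       info = G$info[G$info$snp_id %in% kept, , drop = FALSE]),
                  class = "genotype_matrix")
  list(kept = kept, report = report, genotypes = Gk)
}

#' Merge genotype calls from two platforms
#'
#' Matches SNPs by chromosome + position, resolves allele orientation
#' (direct, swapped, or strand-complemented), computes the discordance
#' fraction over samples called on both platforms, and merges: SNPs with
#' more than `max_discordance` discordant calls are discarded; otherwise
#' discordant calls become missing and concordant or one-sided calls are
#' retained. SNPs unique to one platform are carried over unchanged.
#'
#' @param G1,G2 `genotype_matrix` objects.
#' @param max_discordance Maximum tolerated discordance fraction
#'   (default 0.005).
#' @return A merged `genotype_matrix` over the union of samples and SNPs,
#'   with attribute `"dropped_discordant"` listing discarded SNP ids.
#' @export
merge_platforms <- function(G1, G2, max_discordance = 0.005) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  key1 <- paste(G1$info$chrom, G1$info$pos)
  key2 <- paste(G2$info$chrom, G2$info$pos)
  shared <- intersect(key1, key2)
  samples <- sort(union(rownames(G1$codes), rownames(G2$codes)))
  ssh <- intersect(rownames(G1$codes), rownames(G2$codes))

  take <- function(G, i, samples) {
    v <- rep(NA_integer_, length(samples))
    names(v) <- samples
    v[rownames(G$codes)] <- G$codes[, i]
    v
  }
  dropped <- character()
  cols <- list()
  info <- list()
  for (k in union(key1, key2)) {
    i1 <- match(k, key1)
    i2 <- match(k, key2)
    if (!is.na(i1) && !is.na(i2)) {
      a1 <- c(G1$info$ref[i1], G1$info$alt[i1])
      a2 <- c(G2$info$ref[i2], G2$info$alt[i2])
      g2 <- take(G2, i2, samples)
      if (identical(a1, a2) || identical(a1, unname(comp[a2]))) {
        # orientation agrees
      } else if (identical(a1, rev(a2)) ||
                 identical(a1, unname(comp[rev(a2)]))) {
        g2 <- 2L - g2
      } else {
        stop(sprintf("unresolvable allele mismatch at %s (%s/%s vs %s/%s)",
                     k, a1[1], a1[2], a2[1], a2[2]))
      }
      g1 <- take(G1, i1, samples)
      both <- ssh[!is.na(g1[ssh]) & !is.na(g2[ssh])]
      disc <- if (length(both)) mean(g1[both] != g2[both]) else 0
      if (disc > max_discordance) {
        dropped <- c(dropped, G1$info$snp_id[i1])
        next
      }
      g <- ifelse(is.na(g1), g2, g1)
      g[both[g1[both] != g2[both]]] <- NA_integer_
      cols[[k]] <- g
      info[[k]] <- G1$info[i1, c("snp_id", "chrom", "pos", "ref", "alt")]
    } else if (!is.na(i1)) {
      cols[[k]] <- take(G1, i1, samples)
      info[[k]] <- G1$info[i1, c("snp_id", "chrom", "pos", "ref", "alt")]
    } else {
      cols[[k]] <- take(G2, i2, samples)
      info[[k]] <- G2$info[i2, c("snp_id", "chrom", "pos", "ref", "alt")]
    }
  }
  codes <- do.call(cbind, cols)
  inf <- do.call(rbind, info)
  colnames(codes) <- inf$snp_id
  rownames(inf) <- NULL
  inf$maf <- pmin(colMeans(codes, na.rm = TRUE) / 2,
                  1 - colMeans(codes, na.rm = TRUE) / 2)
  inf$call_rate <- colMeans(!is.na(codes))
  inf$hwe_p <- apply(codes, 2L, function(g) {
    cnt <- tabulate(g + 1L, nbins = 3L)
    hwe_exact_test(cnt[1L], cnt[2L], cnt[3L])
  })
  structure(list(codes = codes, info = inf),
            class = "genotype_matrix") -> out
  attr(out, "dropped_discordant") <- dropped
  out
}

#' Collapse rare homozygote genotype groups
#'
#' Homozygote groups with fewer than `min_count` carriers are combined with
#' the heterozygotes (code 2 recoded to 1; symmetrically, code 0 recoded to
#' 1 when the major homozygote is the rare one). If fewer than two distinct
#' codes remain the pair cannot be tested and a skip signal is returned.
#'
#' @param g Additive genotype vector (0/1/2, `NA` allowed).
#' @param min_count Minimum group size (strict `<` collapses; default 10).
#' @return List: `g` (recoded vector), `collapsed` (logical), `skip`
#'   (logical: fewer than 2 distinct codes remain).
#' @export
collapse_rare_homozygotes <- function(g, min_count = 10L) {
  cnt <- tabulate(g + 1L, nbins = 3L)
  collapsed <- FALSE
  if (cnt[3L] > 0L && cnt[3L] < min_count) {
    g[g == 2L] <- 1L
    collapsed <- TRUE
  }
  if (cnt[1L] > 0L && cnt[1L] < min_count) {
    g[g == 0L] <- 1L
    collapsed <- TRUE
  }
  skip <- length(unique(g[!is.na(g)])) < 2L
  list(g = g, collapsed = collapsed, skip = skip)
}

#' Classify SNP-CpG pairs as proximal or distal
#'
#' A pair is proximal when the SNP and the CpG lie on the same chromosome no
#' more than `window` bp apart (inclusive); otherwise it is distal, split
#' into same-chromosome and inter-chromosome classes.
#'
#' @param snp_chrom,snp_pos,cpg_chrom,cpg_pos Vectors of chromosome names
#'   and 1-based positions (recycled to a common length).
#' @param window Proximal window in bp (default 1e6).
#' @return Character vector in
#'   `{proximal, distal_same_chrom, distal_inter_chrom}`.
#' @examples
#' classify_pair("chr1", 1, "chr1", 1000001)  # proximal (inclusive bound)
#' @export
classify_pair <- function(snp_chrom, snp_pos, cpg_chrom, cpg_pos,
                          window = 1e6) {
  if (any(is.na(snp_chrom)) || any(is.na(cpg_chrom)))
    stop("unknown chromosome")
  same <- snp_chrom == cpg_chrom
  close <- abs(as.numeric(snp_pos) - as.numeric(cpg_pos)) <= window
  ifelse(same & close, "proximal",
         ifelse(same, "distal_same_chrom", "distal_inter_chrom"))
}

# Build a full-rank design matrix (intercept + covariates) on n samples.
# Character columns become factors; rank-deficient columns are dropped with
# a warning.
build_design <- function(X, n) {
  if (is.null(X) || ncol(as.data.frame(X)) == 0L)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.data.frame(X)
  X[] <- lapply(X, function(col) if (is.character(col)) factor(col) else col)
  mm <- stats::model.matrix(~ ., data = X)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    keep <- qrm$pivot[seq_len(qrm$rank)]
    warning(sprintf("dropping %d rank-deficient covariate column(s)",
                    ncol(mm) - qrm$rank))
    mm <- mm[, keep, drop = FALSE]
  }
  mm
}

#' Fit one SNP-CpG association
#'
#' Ordinary least squares for the null model (covariates only) and the full
#' model (covariates + genotype, a single additive predictor). Significance
#' is a likelihood-ratio test, `LRT = n * ln(RSS0 / RSS1)` compared with a
#' chi-squared distribution on 1 df; the effect size is the partial R2,
#' `1 - RSS1 / RSS0`: the proportion of methylation variance explained by
#' the SNP among the variance not already explained by the covariates.
#' Samples missing the outcome, the genotype or any covariate are dropped
#' pairwise.
#'
#' @param y Beta values for one CpG.
#' @param g Recoded genotype vector (see [collapse_rare_homozygotes()]); any
#'   numeric predictor (e.g. imputed dosage) is accepted.
#' @param X Covariate data.frame (sex, age, status, surrogate PCs, batch,
#'   position, ...) or `NULL`.
#' @return One-row data.frame: `n`, `lrt`, `p`, `r2`, `mean0`, `mean1`,
#'   `mean2` (mean beta per genotype code, `NA` for absent codes).
#' @export
fit_pair <- function(y, g, X = NULL) {
  ok <- !is.na(y) & !is.na(g)
  if (!is.null(X)) ok <- ok & stats::complete.cases(X)
  y <- y[ok]
  g <- as.numeric(g[ok])
  n <- length(y)
  mm <- build_design(if (is.null(X)) NULL else X[ok, , drop = FALSE], n)
  if (n - ncol(mm) - 1L < 2L) stop("residual degrees of freedom < 2")
  if (stats::var(g) == 0) stop("genotype is constant after subsetting")
  f0 <- stats::lm.fit(mm, y)
  f1 <- stats::lm.fit(cbind(mm, g = g), y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  if (rss0 <= 0) {
    lrt <- 0; r2 <- 0
  } else {
    lrt <- n * log(rss0 / max(rss1, .Machine$double.xmin))
    r2 <- 1 - rss1 / rss0
  }
  means <- vapply(0:2, function(k) {
    v <- y[g == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  data.frame(n = n, lrt = lrt,
             p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
             r2 = r2, mean0 = means[1L], mean1 = means[2L], mean2 = means[3L])
}

#' Genome-wide SNP-CpG association scan
#'
#' Enumerates SNP-CpG pairs of the requested distance class, fits the
#' covariate-adjusted association model for each (see [fit_pair()]) and
#' streams out the records with `p <= p_cap` together with exact per-class
#' test counts, so that false-discovery control with [scan_fdr()] over the
#' retained tail is identical to full-sort Benjamini-Hochberg whenever the
#' significance cutoff lands below `p_cap`.
#'
#' Rare homozygotes are collapsed per SNP before testing; SNPs left with a
#' single genotype group are skipped and logged. With complete data the scan
#' uses a residualization fast path (both the methylation matrix and the
#' recoded genotypes are regressed on the covariate design once; the partial
#' R2 of a pair is then the squared correlation of the residuals), which is
#' algebraically identical to the per-pair nested OLS fit. With missing
#' values it falls back to per-pair complete-case fits.
#'
#' @param beta Sample x CpG beta matrix (rownames = sample ids).
#' @param G A `genotype_matrix` (QC'd; same samples as `beta`).
#' @param X Covariate data.frame in `beta` sample order, or `NULL`.
#' @param cpg_pos data.frame `cpg_id`, `chrom`, `pos` (a `genome_map` is
#'   also accepted).
#' @param mode `"all"`, `"proximal"` or `"distal"` (both distal classes).
#' @param window Proximal window in bp.
#' @param p_cap Emit only records with `p <= p_cap` (default 1: all).
#' @param min_hom Passed to [collapse_rare_homozygotes()].
#' @param na_action How to handle missing values: `"pairwise"` (default)
#'   fits every pair on its complete cases — exact but one OLS fit per
#'   pair; `"impute"` replaces missing beta values and genotype calls by
#'   their site/SNP means so the residualization fast path applies —
#'   appropriate at genome scale when missingness is sparse (QC bounds it
#'   at ~1% per probe), at the cost of slightly attenuated statistics for
#'   affected pairs.
#' @return Object of class `meqtl_scan`: `records` (data.frame `snp_id`,
#'   `cpg_id`, `class`, `n`, `lrt`, `p`, `r2`, `mean0..2`, `collapsed`),
#'   `counts` (tests per class over analyzed SNPs), `skipped` (SNP ids),
#'   `n_samples`, `p_cap`, `mode`, `window`.
#' @export
meqtl_scan <- function(beta, G, X = NULL, cpg_pos,
                       mode = c("all", "proximal", "distal"),
                       window = 1e6, p_cap = 1, min_hom = 10L,
                       na_action = c("pairwise", "impute")) {
  mode <- match.arg(mode)
  na_action <- match.arg(na_action)
  if (inherits(cpg_pos, "genome_map")) cpg_pos <- cpg_pos$cpgs
  codes <- G$codes
  if (is.null(rownames(beta)) || is.null(rownames(codes)) ||
      !setequal(rownames(beta), rownames(codes)))
    stop("sample id mismatch between beta and genotype matrices")
  codes <- codes[rownames(beta), , drop = FALSE]
  cpgs <- intersect(colnames(beta), cpg_pos$cpg_id)
  if (length(cpgs) == 0L) stop("no CpG ids shared with the position table")
  beta <- beta[, cpgs, drop = FALSE]
  cpg_pos <- cpg_pos[match(cpgs, cpg_pos$cpg_id), ]
  info <- G$info[match(colnames(codes), G$info$snp_id), ]
  n <- nrow(beta)

  # collapse rare homozygotes once per SNP
  Grec <- matrix(NA_real_, n, ncol(codes), dimnames = dimnames(codes))
  collapsed <- logical(ncol(codes))
  skip <- logical(ncol(codes))
  for (j in seq_len(ncol(codes))) {
    cr <- collapse_rare_homozygotes(codes[, j], min_hom)
    Grec[, j] <- cr$g
    collapsed[j] <- cr$collapsed
    skip[j] <- cr$skip
  }
  keep <- !skip
  Grec <- Grec[, keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  collapsed <- collapsed[keep]
  S <- ncol(Grec); C <- ncol(beta)
  if (S == 0L) stop("no polymorphic SNPs to test")

  # SNP x CpG distance classes and per-class candidate counts
  cls <- matrix(3L, S, C)  # 1 proximal, 2 distal same chrom, 3 inter chrom
  for (ch in unique(info$chrom)) {
    si <- which(info$chrom == ch)
    ci <- which(cpg_pos$chrom == ch)
    if (!length(si) || !length(ci)) next
    d <- abs(outer(info$pos[si], cpg_pos$pos[ci], "-"))
    cls[si, ci] <- ifelse(d <= window, 1L, 2L)
  }
  class_names <- c("proximal", "distal_same_chrom", "distal_inter_chrom")
  counts <- stats::setNames(tabulate(cls, nbins = 3L), class_names)

  want <- switch(mode, all = 1:3, proximal = 1L, distal = 2:3)
  if (na_action == "impute") {
    impute_cols <- function(m) {
      mu <- colMeans(m, na.rm = TRUE)
      idx <- which(is.na(m), arr.ind = TRUE)
      if (nrow(idx)) m[idx] <- mu[idx[, 2L]]
      m
    }
    beta <- impute_cols(beta)
    Grec <- impute_cols(Grec)
  }
  X_design_ok <- is.null(X) || !anyNA(X)
  complete <- !anyNA(beta) && !anyNA(Grec) && X_design_ok

  if (complete) {
    Q <- build_design(X, n)
    if (n - ncol(Q) - 1L < 2L) stop("residual degrees of freedom < 2")
    qrQ <- qr(Q)
    Yr <- qr.resid(qrQ, beta)
    Gr <- qr.resid(qrQ, Grec)
    yn <- sqrt(colSums(Yr^2))
    gn <- sqrt(colSums(Gr^2))
    r <- crossprod(sweep(Gr, 2L, pmax(gn, .Machine$double.eps), "/"),
                   sweep(Yr, 2L, pmax(yn, .Machine$double.eps), "/"))
    r2 <- r * r
    r2[r2 > 1] <- 1
    lrt <- -n * log1p(-r2)
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    sel <- which(p <= p_cap & matrix(cls %in% want, S, C))
    si <- ((sel - 1L) %% S) + 1L
    ci <- ((sel - 1L) %/% S) + 1L
    recs <- data.frame(
      snp_id = info$snp_id[si], cpg_id = cpg_pos$cpg_id[ci],
      class = class_names[cls[sel]], n = n,
      lrt = lrt[sel], p = p[sel], r2 = r2[sel],
      mean0 = NA_real_, mean1 = NA_real_, mean2 = NA_real_,
      collapsed = collapsed[si], stringsAsFactors = FALSE)
    for (k in seq_len(nrow(recs))) {
      y <- beta[, ci[k]]
      g <- Grec[, si[k]]
      for (code in 0:2) {
        v <- y[g == code]
        recs[[paste0("mean", code)]][k] <-
          if (length(v)) mean(v) else NA_real_
      }
    }
  } else {
    rows <- list()
    ri <- 0L
    for (j in seq_len(S)) {
      for (cc in seq_len(C)) {
        if (!(cls[j, cc] %in% want)) next
        rec <- tryCatch(fit_pair(beta[, cc], Grec[, j], X),
                        error = function(e) NULL)
        if (is.null(rec) || rec$p > p_cap) next
        ri <- ri + 1L
        rows[[ri]] <- cbind(
          data.frame(snp_id = info$snp_id[j], cpg_id = cpg_pos$cpg_id[cc],
                     class = class_names[cls[j, cc]],
                     stringsAsFactors = FALSE),
          rec, collapsed = collapsed[j])
      }
    }
    recs <- if (ri) do.call(rbind, rows) else
      data.frame(snp_id = character(), cpg_id = character(),
                 class = character(), n = integer(), lrt = numeric(),
                 p = numeric(), r2 = numeric(), mean0 = numeric(),
                 mean1 = numeric(), mean2 = numeric(),
                 collapsed = logical(), stringsAsFactors = FALSE)
  }
  rownames(recs) <- NULL
  structure(list(records = recs, counts = counts,
                 skipped = colnames(codes)[!keep], n_samples = n,
                 p_cap = p_cap, mode = mode, window = window),
            class = "meqtl_scan")
}

#' @export
print.meqtl_scan <- function(x, ...) {
  cat(sprintf("meqtl_scan: %d samples, %s candidate pairs (%s), %d record(s) at p <= %g\n",
              x$n_samples, format(sum(x$counts), big.mark = ","),
              paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
              nrow(x$records), x$p_cap))
  invisible(x)
}
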