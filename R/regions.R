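# Internal interval helpers. Intervals are 1-based inclusive data.frames
# (chrom, start, end). Contiguous integer intervals are unioned
# ([1,10] + [11,20] -> [1,20]), matching per-base span semantics. These run
# inside the resampling loop, so they are plain sort-and-sweep / findInterval
# operations.

merge_intervals_1chrom <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- numeric(length(start)); me <- numeric(length(start))
  k <- 0L
  for (i in seq_along(start)) {
    if (k > 0L && start[i] <= me[k] + 1) {
      if (end[i] > me[k]) me[k] <- end[i]
    } else {
      k <- k + 1L
      ms[k] <- start[i]; me[k] <- end[i]
    }
  }
  list(start = ms[seq_len(k)], end = me[seq_len(k)])
}

# count features overlapping (>= 1 bp) a set of disjoint sorted intervals
count_overlaps_sorted <- function(f_start, f_end, m_start, m_end) {
  if (length(m_start) == 0L || length(f_start) == 0L) return(0L)
  idx <- findInterval(f_end, m_start)      # last interval with start <= f_end
  sum(idx >= 1L & m_end[pmax(idx, 1L)] >= f_start)
}

#' Build the LD-defined region around each SNP
#'
#' For each index SNP, the smallest genomic region containing the SNP and
#' every partner in high LD with it (squared correlation strictly greater
#' than `r2_min`): the interval from the minimum to the maximum position of
#' the set. A SNP with no qualifying partner yields the degenerate interval
#' `[pos, pos]`.
#'
#' @param snps Character vector of index SNP ids.
#' @param snp_pos data.frame `snp_id`, `chrom`, `pos` covering the index
#'   SNPs and their LD partners (a `genome_map` is accepted).
#' @param ld data.frame `snp_a`, `snp_b`, `r2` (unordered pairs; treated as
#'   symmetric).
#' @param r2_min LD threshold (strict `>`; default 0.5).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `index_snp`.
#' @export
ld_regions <- function(snps, snp_pos, ld, r2_min = 0.5) {
  if (inherits(snp_pos, "genome_map")) snp_pos <- snp_pos$snps
  ix <- match(snps, snp_pos$snp_id)
  if (anyNA(ix)) stop("SNP absent from the position map: ",
                      paste(snps[is.na(ix)], collapse = ", "))
  keep <- ld$r2 > r2_min
  partners <- rbind(
    data.frame(a = ld$snp_a[keep], b = ld$snp_b[keep]),
    data.frame(a = ld$snp_b[keep], b = ld$snp_a[keep]))
  pmap <- split(partners$b, partners$a)
  out <- data.frame(chrom = snp_pos$chrom[ix], start = snp_pos$pos[ix],
                    end = snp_pos$pos[ix], index_snp = snps,
                    stringsAsFactors = FALSE)
  for (i in seq_along(snps)) {
    pr <- pmap[[snps[i]]]
    if (is.null(pr)) next
    pp <- snp_pos$pos[match(pr, snp_pos$snp_id)]
    pc <- snp_pos$chrom[match(pr, snp_pos$snp_id)]
    pp <- pp[!is.na(pp) & pc == out$chrom[i]]
    if (length(pp)) {
      out$start[i] <- min(out$start[i], pp)
      out$end[i] <- max(out$end[i], pp)
    }
  }
  out
}

#' Merge regions into a non-overlapping set
#'
#' Per-chromosome interval union. The total span is the number of bases
#' covered, so two contiguous intervals merge into one.
#'
#' @param regions data.frame `chrom`, `start`, `end` (1-based inclusive);
#'   extra columns are allowed (index SNPs are aggregated when present).
#' @return List: `regions` (merged, with `merged_from` counts), `n`,
#'   `total_span_bp`, `total_span_mb`.
#' @export
merge_regions <- function(regions) {
  out <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    m <- merge_intervals_1chrom(r$start, r$end)
    nfrom <- vapply(seq_along(m$start), function(i)
      sum(r$start <= m$end[i] & r$end >= m$start[i]), 0L)
    out[[ch]] <- data.frame(chrom = ch, start = m$start, end = m$end,
                            merged_from = nfrom, stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, out)
  if (is.null(merged))
    merged <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), merged_from = integer())
  rownames(merged) <- NULL
  span <- sum(merged$end - merged$start + 1)
  list(regions = merged, n = nrow(merged), total_span_bp = span,
       total_span_mb = span / 1e6)
}

# strand-aware promoter extension of gene-like tracks
extend_promoters <- function(track, promoter_ext, promoter_classes) {
  ext <- track$class %in% promoter_classes
  if (promoter_ext > 0 && any(ext)) {
    if (is.null(track$strand) || anyNA(track$strand[ext]))
      stop("strandless track cannot receive a promoter extension")
    plus <- ext & track$strand == "+"
    minus <- ext & track$strand == "-"
    track$start[plus] <- pmax(1, track$start[plus] - promoter_ext)
    track$end[minus] <- track$end[minus] + promoter_ext
  }
  track
}

#' Count features in a region set
#'
#' Counts, per feature class, the features falling at least partially (>= 1
#' bp overlap) inside the merged region set. Gene-class features are first
#' extended by `promoter_ext` bp upstream of their transcription start
#' (strand-aware). Each feature is counted at most once.
#'
#' @param regions Merged regions (data.frame `chrom`, `start`, `end`) or the
#'   result of [merge_regions()].
#' @param track Feature track: data.frame `chrom`, `start`, `end`, `class`,
#'   optional `strand`, `name`.
#' @param promoter_ext Upstream extension in bp applied to
#'   `promoter_classes` (default 5000).
#' @param promoter_classes Track classes treated as genes (default
#'   `"gene"`).
#' @return List: `counts` (named per-class feature counts), `hits` (logical
#'   vector over track rows).
#' @export
annotate_regions <- function(regions, track, promoter_ext = 5000,
                             promoter_classes = "gene") {
  if (is.list(regions) && !is.data.frame(regions)) regions <- regions$regions
  track <- extend_promoters(track, promoter_ext, promoter_classes)
  hits <- logical(nrow(track))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    m <- merge_intervals_1chrom(r$start, r$end)
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    idx <- findInterval(track$end[ti], m$start)
    hits[ti] <- idx >= 1L & m$end[pmax(idx, 1L)] >= track$start[ti]
  }
  cls <- unique(track$class)
  counts <- vapply(cls, function(k) sum(hits[track$class == k]), 0L)
  list(counts = counts, hits = hits)
}

#' Feature enrichment in meQTL regions by SNP resampling
#'
#' Compares the observed feature density (features per Mb) of the merged
#' LD-defined regions around the index SNPs against a null built by
#' repeatedly sampling the same number of SNPs, without replacement, from
#' the pool of all SNPs that entered the association analysis, and building
#' and merging their LD regions the same way. The fold enrichment is the
#' observed density divided by the mean null density; significance is the
#' proportion of replicates whose feature *count* is greater than or equal
#' to the observed count, reported as `< 1/R` when no replicate reaches it.
#'
#' @param index_snps Character vector of observed index SNP ids.
#' @param track Feature track (see [annotate_regions()]).
#' @param snp_pool Character vector: all analyzed SNP ids (the sampling
#'   frame; not genome-wide).
#' @param snp_pos,ld,r2_min Passed to [ld_regions()].
#' @param R Number of resampling replicates (default 1000).
#' @param seed Integer seed.
#' @param promoter_ext,promoter_classes Passed to [annotate_regions()].
#' @return data.frame, one row per feature class: `class`, `observed_count`,
#'   `observed_density`, `mean_null_density`, `fold`, `p`, `p_label`, `R`.
#'   `fold` is `NA` when both observed and null are empty (with `p = 1`).
#'   Attribute `"null_counts"` holds the per-replicate count matrix.
#' @export
enrichment_test <- function(index_snps, track, snp_pool, snp_pos, ld,
                            r2_min = 0.5, R = 1000L, seed = 1L,
                            promoter_ext = 5000, promoter_classes = "gene") {
  if (R < 1L) stop("R must be at least 1")
  if (length(snp_pool) < length(index_snps))
    stop("SNP pool smaller than the number of index SNPs")
  if (inherits(snp_pos, "genome_map")) snp_pos <- snp_pos$snps

  # precompute every pool (and index) SNP's LD region and the extended
  # track once; replicates then only merge and count
  pool_regions <- ld_regions(unique(c(snp_pool, index_snps)), snp_pos, ld,
                             r2_min)
  rownames(pool_regions) <- pool_regions$index_snp
  trk <- extend_promoters(track, promoter_ext, promoter_classes)
  cls <- unique(trk$class)
  trk_by <- split(seq_len(nrow(trk)), trk$chrom)

  count_set <- function(snp_ids) {
    reg <- pool_regions[snp_ids, , drop = FALSE]
    span <- 0
    counts <- stats::setNames(numeric(length(cls)), cls)
    for (ch in unique(reg$chrom)) {
      r <- reg[reg$chrom == ch, , drop = FALSE]
      m <- merge_intervals_1chrom(r$start, r$end)
      span <- span + sum(m$end - m$start + 1)
      ti <- trk_by[[ch]]
      if (is.null(ti)) next
      idx <- findInterval(trk$end[ti], m$start)
      hit <- idx >= 1L & m$end[pmax(idx, 1L)] >= trk$start[ti]
      if (any(hit)) {
        tb <- table(trk$class[ti][hit])
        counts[names(tb)] <- counts[names(tb)] + tb
      }
    }
    list(counts = counts, span_mb = span / 1e6)
  }

  obs <- count_set(index_snps)

  null_counts <- matrix(0, R, length(cls), dimnames = list(NULL, cls))
  null_dens <- matrix(0, R, length(cls), dimnames = list(NULL, cls))
  with_seed(substream(seed, 7L), {
    for (r in seq_len(R)) {
      smp <- sample(snp_pool, length(index_snps))
      cs <- count_set(smp)
      null_counts[r, ] <- cs$counts
      null_dens[r, ] <- if (cs$span_mb > 0) cs$counts / cs$span_mb else 0
    }
  })
  obs_dens <- if (obs$span_mb > 0) obs$counts / obs$span_mb else
    stats::setNames(rep(0, length(cls)), cls)
  mean_null <- colMeans(null_dens)
  fold <- ifelse(obs_dens == 0 & mean_null == 0, NA_real_,
                 obs_dens / mean_null)
  k <- vapply(cls, function(ci)
    sum(null_counts[, ci] >= obs$counts[ci]), 0)
  p <- ifelse(obs$counts == 0 & colSums(null_counts) == 0, 1, k / R)
  out <- data.frame(
    class = cls, observed_count = as.numeric(obs$counts),
    observed_density = as.numeric(obs_dens),
    mean_null_density = as.numeric(mean_null),
    fold = as.numeric(fold), p = as.numeric(p),
    p_label = ifelse(p == 0, paste0("< 1/", R), format(p, digits = 3)),
    R = R, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_counts") <- null_counts
  attr(out, "observed_span_mb") <- obs$span_mb
  out
}

#' Fraction of regions near chromosome ends
#'
#' A region is subtelomeric when any part of it lies within `margin` bp of
#' position 1 or of the chromosome end.
#'
#' @param regions data.frame `chrom`, `start`, `end`.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param margin Distance from the ends in bp (default 2e6).
#' @return List: `count`, `fraction`, `subtelomeric` (logical per region).
#' @export
subtelomeric_fraction <- function(regions, chrom_lengths, margin = 2e6) {
  len <- chrom_lengths[regions$chrom]
  if (anyNA(len)) stop("region on a chromosome of unknown length")
  if (any(regions$end > len)) stop("region beyond chromosome length")
  sub <- unname(regions$start <= margin | regions$end >= len - margin + 1)
  list(count = sum(sub), fraction = sum(sub) / nrow(regions),
       subtelomeric = sub)
}

#' Annotate CpG sites to genes
#'
#' A CpG maps to every gene whose interval from 1,500 bp upstream of the
#' transcription start site through the end of the 3' UTR (strand-aware)
#' contains it; overlapping genes all report.
#'
#' @param cpgs data.frame `cpg_id`, `chrom`, `pos`.
#' @param genes data.frame `name` (or `gene`), `chrom`, `start`, `end`,
#'   `strand` (TSS = `start` on "+", `end` on "-").
#' @param tss_window Upstream window in bp (default 1500).
#' @return data.frame `cpg_id`, `gene` (zero or more rows per CpG).
#' @export
annotate_cpg_genes <- function(cpgs, genes, tss_window = 1500) {
  gname <- if (!is.null(genes$gene)) genes$gene else genes$name
  if (is.null(gname) || is.null(genes$strand) ||
      anyNA(genes$start) || anyNA(genes$end))
    stop("malformed gene record")
  lo <- ifelse(genes$strand == "+", genes$start - tss_window, genes$start)
  hi <- ifelse(genes$strand == "+", genes$end, genes$end + tss_window)
  out <- list()
  for (i in seq_len(nrow(cpgs))) {
    hit <- genes$chrom == cpgs$chrom[i] & cpgs$pos[i] >= lo &
      cpgs$pos[i] <= hi
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        cpg_id = cpgs$cpg_id[i], gene = gname[hit], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cpg_id = character(), gene = character())
  rownames(res) <- NULL
  res
}
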