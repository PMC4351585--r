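#' Build a synthetic genome coordinate map
#'
#' Lays out SNPs and CpG sites on one or more chromosomes and groups
#' consecutive SNPs into LD blocks. Within a block, genotypes simulated by
#' [simulate_genotypes()] share a latent haplotype so that pairwise LD
#' (squared allele-count correlation) is high; across blocks it is zero by
#' construction. The map is the coordinate system every downstream distance
#' rule (the 1-Mb proximal window, subtelomeric margins, LD regions) runs on.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp (recycled across chromosomes).
#' @param n_snps,n_cpgs Total numbers of loci, split as evenly as possible
#'   across chromosomes.
#' @param ld_block_size Number of consecutive SNPs per LD block (the last
#'   block on a chromosome may be smaller).
#' @param seed Integer seed; identical inputs and seed give an identical map.
#' @param flip_prob Per-SNP probability that a haplotype's allele differs from
#'   the block's latent haplotype; controls within-block LD strength.
#' @return An object of class `genome_map`: a list with `chromosomes`
#'   (data.frame `chrom`, `length`), `snps` (`snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `block`), `cpgs` (`cpg_id`, `chrom`, `pos`), `ld_blocks` (list of
#'   SNP-id character vectors) and `flip_prob`.
#' @examples
#' map <- make_genome_map(2, 5e6, 40, 60, ld_block_size = 5, seed = 1)
#' map
#' @export
make_genome_map <- function(n_chrom, chrom_length, n_snps, n_cpgs,
                            ld_block_size, seed, flip_prob = 0.02) {
  stopifnot(n_chrom >= 1, n_snps >= 1, n_cpgs >= 1, ld_block_size >= 1,
            chrom_length >= 1)
  chrom_length <- rep_len(as.numeric(chrom_length), n_chrom)
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length = chrom_length, stringsAsFactors = FALSE)
  # split loci as evenly as possible across chromosomes
  split_counts <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + (seq_len(k) <= extra)
  }
  n_snp_c <- split_counts(n_snps, n_chrom)
  n_cpg_c <- split_counts(n_cpgs, n_chrom)
  if (any(n_snp_c + n_cpg_c > chrom_length))
    stop("more loci requested than positions available on a chromosome")

  with_seed(seed, {
    snps <- vector("list", n_chrom)
    cpgs <- vector("list", n_chrom)
    for (c in seq_len(n_chrom)) {
      # draw SNP and CpG positions jointly without replacement so ids never
      # collide on a shared base
      pos <- sample.int(chrom_length[c], n_snp_c[c] + n_cpg_c[c])
      sp <- sort(pos[seq_len(n_snp_c[c])])
      cp <- sort(pos[n_snp_c[c] + seq_len(n_cpg_c[c])])
      snps[[c]] <- data.frame(chrom = chroms$chrom[c], pos = sp,
                              stringsAsFactors = FALSE)
      cpgs[[c]] <- data.frame(chrom = chroms$chrom[c], pos = cp,
                              stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, snps)
    cpgs <- do.call(rbind, cpgs)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(snps), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    snps <- data.frame(
      snp_id = sprintf("snp%05d", seq_len(nrow(snps))),
      snps, ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
    cpgs <- data.frame(
      cpg_id = sprintf("cg%05d", seq_len(nrow(cpgs))),
      cpgs, stringsAsFactors = FALSE)

    # consecutive SNPs per chromosome form LD blocks
    block <- integer(nrow(snps))
    nb <- 0L
    for (c in chroms$chrom) {
      idx <- which(snps$chrom == c)
      b <- (seq_along(idx) - 1L) %/% ld_block_size + 1L
      block[idx] <- nb + b
      nb <- nb + max(b)
    }
    snps$block <- block
    ld_blocks <- split(snps$snp_id, snps$block)
    names(ld_blocks) <- NULL

    structure(list(chromosomes = chroms, snps = snps, cpgs = cpgs,
                   ld_blocks = ld_blocks, flip_prob = flip_prob),
              class = "genome_map")
  })
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosome(s), %d SNPs, %d CpGs, %d LD blocks\n",
              nrow(x$chromosomes), nrow(x$snps), nrow(x$cpgs),
              length(x$ld_blocks)))
  invisible(x)
}

#' Empirical LD table from simulated genotypes
#'
#' Computes the squared allele-count correlation (R2) for every within-block
#' SNP pair of a [genome map][make_genome_map], from a genotype matrix.
#' Cross-block pairs are omitted (R2 is zero by construction of the
#' generator). The result is the `(snp_a, snp_b, r2)` table consumed by
#' [ld_regions()] and [enrichment_test()].
#'
#' @param map A `genome_map`.
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @return data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
ld_table <- function(map, genotypes) {
  stopifnot(inherits(map, "genome_map"))
  codes <- genotypes$codes
  out <- vector("list", length(map$ld_blocks))
  for (b in seq_along(map$ld_blocks)) {
    ids <- intersect(map$ld_blocks[[b]], colnames(codes))
    if (length(ids) < 2L) next
    r <- suppressWarnings(stats::cor(codes[, ids, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    pr <- which(upper.tri(r), arr.ind = TRUE)
    out[[b]] <- data.frame(snp_a = ids[pr[, 1L]], snp_b = ids[pr[, 2L]],
                           r2 = r[pr]^2, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  res$r2[is.na(res$r2)] <- 0
  rownames(res) <- NULL
  res
}
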