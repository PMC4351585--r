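# Text I/O in the pipeline's TSV dialects. Matrices are written samples as
# rows; BED conversion happens at the boundary (1-based inclusive inside,
# 0-based half-open on disk).

#' Read and write pipeline matrices and tracks
#'
#' `write_matrix_tsv()` / `read_matrix_tsv()` handle sample x feature
#' matrices (beta, intensities, detection scores, dosages) with sample ids
#' in the first column. `write_bed()` / `read_bed()` convert feature tracks
#' between the package's 1-based inclusive data.frames and BED's 0-based
#' half-open intervals, carrying the class in column 7. `write_genotype_tsv()`
#' / `read_genotype_tsv()` serialize a `genotype_matrix` as a pair of files
#' (codes + SNP info). `write_vcf()` emits a minimal VCF 4.2 with GT fields;
#' `read_vcf()` (requires the vcfR package) recodes GT against the minor
#' allele.
#'
#' @param x Object to write.
#' @param path File path (for genotypes, a stem producing
#'   `<stem>.codes.tsv` and `<stem>.info.tsv`).
#' @return Readers return the reconstructed object; writers return the path
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname pipeline_io
#' @export
write_bed <- function(x, path) {
  bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end,
                    name = if (!is.null(x$name)) x$name else ".",
                    score = 0L,
                    strand = if (!is.null(x$strand)) x$strand else ".",
                    class = if (!is.null(x$class)) x$class else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "class")[1:7],
                           fill = TRUE)
  data.frame(chrom = as.character(bed$chrom), start = bed$start + 1L,
             end = bed$end, name = as.character(bed$name),
             class = as.character(bed$class),
             strand = as.character(bed$strand), stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
write_genotype_tsv <- function(x, path) {
  write_matrix_tsv(x$codes, paste0(path, ".codes.tsv"))
  utils::write.table(x$info, paste0(path, ".info.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_genotype_tsv <- function(path) {
  codes <- read_matrix_tsv(paste0(path, ".codes.tsv"))
  mode(codes) <- "integer"
  info <- utils::read.delim(paste0(path, ".info.tsv"))
  structure(list(codes = codes, info = info), class = "genotype_matrix")
}

#' @rdname pipeline_io
#' @export
write_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(x$codes)),
                     collapse = "\t")), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(x$codes))) {
    g <- x$codes[, j]
    gt <- ifelse(is.na(g), "./.", gt_of[g + 1L])
    writeLines(paste(c(x$info$chrom[j], x$info$pos[j], x$info$snp_id[j],
                       x$info$ref[j], x$info$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  codes <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1L]]))
  })
  codes <- t(codes)
  fx <- vcfR::getFIX(v)
  info <- data.frame(snp_id = fx[, "ID"], chrom = fx[, "CHROM"],
                     pos = as.integer(fx[, "POS"]), ref = fx[, "REF"],
                     alt = fx[, "ALT"], stringsAsFactors = FALSE)
  # recode against the minor allele
  f <- colMeans(codes, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  codes[, flip] <- 2L - codes[, flip]
  info$maf <- pmin(colMeans(codes, na.rm = TRUE) / 2,
                   1 - colMeans(codes, na.rm = TRUE) / 2)
  info$call_rate <- colMeans(!is.na(codes))
  info$hwe_p <- apply(codes, 2L, function(g) {
    cnt <- tabulate(g + 1L, nbins = 3L)
    hwe_exact_test(cnt[1L], cnt[2L], cnt[3L])
  })
  rownames(info) <- NULL
  structure(list(codes = codes, info = info), class = "genotype_matrix")
}
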