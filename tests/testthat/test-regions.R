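test_that("LD regions span the index SNP and its strict-threshold partners", {
  snp_pos <- data.frame(snp_id = c("s1", "s2", "s3", "s4", "s5"),
                        chrom = "chr1",
                        pos = c(300e3, 100e3, 500e3, 900e3, 950e3))
  ld <- data.frame(snp_a = c("s1", "s1", "s1", "s1"),
                   snp_b = c("s2", "s3", "s4", "s5"),
                   r2 = c(0.9, 0.7, 0.6, 0.5))
  r <- ld_regions("s1", snp_pos, ld)
  expect_equal(c(r$start, r$end), c(100e3, 900e3))  # s5 at exactly 0.5 out
  # no partners -> degenerate interval
  r3 <- ld_regions("s3", snp_pos, ld[ld$r2 > 0.95, ])
  expect_equal(c(r3$start, r3$end), c(500e3, 500e3))
  expect_error(ld_regions("nope", snp_pos, ld), "absent")
})

test_that("region merging equals a per-base bitmap oracle", {
  m <- merge_regions(data.frame(chrom = "chr1", start = c(1, 5),
                                end = c(10, 20)))
  expect_equal(nrow(m$regions), 1)
  expect_equal(m$total_span_bp, 20)
  disj <- merge_regions(data.frame(chrom = "chr1", start = c(1, 100),
                                   end = c(10, 120)))
  expect_equal(nrow(disj$regions), 2)
  expect_equal(disj$total_span_bp, 31)
  set.seed(20)
  for (rep in 1:5) {
    n <- 1000
    start <- sample.int(50000, n, replace = TRUE)
    end <- pmin(start + sample.int(500, n, replace = TRUE), 60000)
    mm <- merge_regions(data.frame(chrom = "chrZ", start = start, end = end))
    bitmap <- logical(60000)
    for (i in seq_len(n)) bitmap[start[i]:end[i]] <- TRUE
    expect_equal(mm$total_span_bp, sum(bitmap))
    expect_equal(nrow(mm$regions), sum(diff(c(FALSE, bitmap)) == 1))
    # idempotence and order invariance
    mm2 <- merge_regions(mm$regions)
    expect_equal(mm2$regions$start, mm$regions$start)
    o <- sample(n)
    mm3 <- merge_regions(data.frame(chrom = "chrZ", start = start[o],
                                    end = end[o]))
    expect_equal(mm3$regions, mm$regions)
  }
})

test_that("region merging agrees with IRanges reduce", {
  skip_if_not_installed("IRanges")
  set.seed(21)
  start <- sample.int(1e5, 300, replace = TRUE)
  end <- start + sample.int(1000, 300, replace = TRUE)
  m <- merge_regions(data.frame(chrom = "chr1", start = start, end = end))
  ir <- IRanges::reduce(IRanges::IRanges(start, end))
  expect_equal(m$regions$start, IRanges::start(ir))
  expect_equal(m$regions$end, IRanges::end(ir))
  expect_equal(m$total_span_bp, sum(IRanges::width(ir)))
})

test_that("feature counting applies strand-aware promoter extension", {
  regions <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  track <- data.frame(
    chrom = "chr1",
    start = c(4000, 22000, 12000, 4000),
    end = c(6999, 24999, 12500, 6999),
    name = c("away_plus", "near_minus", "inside", "near_minus_b"),
    class = "gene",
    strand = c("+", "-", "+", "-"))
  # + gene ending 3 kb before the region extends upstream (leftward): no hit;
  # - gene starting 2 kb after the region end extends rightward at its TSS
  # side... its extension goes right, so reaching back is via gene 4:
  # - strand gene ending 3 kb before region start extends right by 5 kb -> hit
  ann <- annotate_regions(regions, track, promoter_ext = 5000)
  expect_equal(unname(ann$counts["gene"]), 2)
  expect_equal(ann$hits, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(annotate_regions(regions, transform(track, strand = NA),
                                promoter_ext = 5000), "strandless")
  # brute-force all-pairs overlap oracle on random fixtures
  set.seed(22)
  for (rep in 1:5) {
    regs <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                       start = sample.int(1e5, 30, TRUE))
    regs$end <- regs$start + sample.int(5000, 30, TRUE)
    trk <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                      start = sample.int(1.1e5, 200, TRUE),
                      class = "feat", strand = "+")
    trk$end <- trk$start + sample.int(2000, 200, TRUE)
    got <- annotate_regions(regs, trk, promoter_ext = 0)
    oracle <- vapply(seq_len(200), function(i) {
      any(trk$chrom[i] == regs$chrom & trk$start[i] <= regs$end &
            trk$end[i] >= regs$start)
    }, TRUE)
    expect_identical(got$hits, oracle)
    expect_equal(unname(got$counts["feat"]), sum(oracle))
  }
})

test_that("enrichment resampling is calibrated on unenriched tracks", {
  map <- make_genome_map(4, 1e7, 200, 20, 5, seed = 31)
  G <- simulate_genotypes(map, 400, c(0.1, 0.5), 0, seed = 32)
  ld <- ld_table(map, G)
  trk <- make_feature_tracks(map, c(feat = 300), NULL, 1, seed = 33)
  idx <- with_seed(34, sample(map$snps$snp_id, 25))
  er <- enrichment_test(idx, trk, map$snps$snp_id, map, ld, R = 400,
                        seed = 35, promoter_ext = 0)
  expect_equal(er$fold, 1, tolerance = 0.15)
  expect_gt(er$p, 0.05)
  expect_lt(er$p, 0.95)
})

test_that("planted enrichment is detected with an extreme empirical p", {
  map <- make_genome_map(4, 1e7, 200, 20, 5, seed = 41)
  G <- simulate_genotypes(map, 400, c(0.1, 0.5), 0, seed = 42)
  ld <- ld_table(map, G)
  idx <- with_seed(43, sample(map$snps$snp_id, 30))
  obs <- merge_regions(ld_regions(idx, map, ld))
  # widen the planted zone around the observed regions so features land
  # densely where the index SNPs live
  zone <- obs$regions
  zone$start <- pmax(1, zone$start - 2e4)
  zone$end <- zone$end + 2e4
  trk <- make_feature_tracks(map, c(feat = 400), zone,
                             enrichment_factor = 8, seed = 44)
  er <- enrichment_test(idx, trk, map$snps$snp_id, map, ld, R = 1000,
                        seed = 45, promoter_ext = 0)
  expect_gt(er$fold, 1.5)
  expect_equal(er$p, 0)
  expect_equal(er$p_label, "< 1/1000")
})

test_that("degenerate enrichment inputs report missing fold and p = 1", {
  map <- make_genome_map(1, 1e6, 20, 5, 5, seed = 51)
  ld <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  trk <- data.frame(chrom = "chr1", start = 1, end = 2, name = "f",
                    class = "feat", strand = "+")
  trk <- trk[0, ]  # zero features of the class
  trk <- rbind(trk, data.frame(chrom = "chrQ", start = 1, end = 2,
                               name = "f", class = "feat", strand = "+"))
  er <- enrichment_test(map$snps$snp_id[1:3], trk, map$snps$snp_id, map, ld,
                        R = 50, seed = 52, promoter_ext = 0)
  expect_true(is.na(er$fold))
  expect_equal(er$p, 1)
  expect_error(enrichment_test(map$snps$snp_id[1:3], trk,
                               map$snps$snp_id[1:2], map, ld, R = 50,
                               seed = 1), "pool smaller")
})

test_that("subtelomeric classification uses a 2 Mb margin from either end", {
  lens <- c(chr1 = 1e8)
  sub <- subtelomeric_fraction(
    data.frame(chrom = "chr1", start = c(5e5, 5e7, 9.85e7),
               end = c(1e6, 5.05e7, 9.9e7)), lens)
  expect_equal(sub$subtelomeric, c(TRUE, FALSE, TRUE))
  expect_equal(sub$count, 2)
  expect_equal(sub$fraction, 2 / 3)
  expect_error(subtelomeric_fraction(
    data.frame(chrom = "chr1", start = 1, end = 2e8), lens), "beyond")
})

test_that("CpG-to-gene annotation honors the TSS window and 3' UTR end", {
  genes <- data.frame(name = c("gplus", "gminus", "gover"),
                      chrom = "chr1",
                      start = c(10000, 50000, 11000),
                      end = c(20000, 60000, 21000),
                      strand = c("+", "-", "+"))
  cpgs <- data.frame(cpg_id = c("c_up1000", "c_up2000", "c_in_two",
                                "c_minus_up"),
                     chrom = "chr1",
                     pos = c(9000, 8000, 11000, 61000))
  ann <- annotate_cpg_genes(cpgs, genes)
  expect_setequal(ann$gene[ann$cpg_id == "c_up1000"], "gplus")
  expect_false("c_up2000" %in% ann$cpg_id)
  expect_setequal(ann$gene[ann$cpg_id == "c_in_two"], c("gplus", "gover"))
  expect_setequal(ann$gene[ann$cpg_id == "c_minus_up"], "gminus")
  expect_error(annotate_cpg_genes(cpgs, transform(genes, strand = NULL)),
               "malformed")
})
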