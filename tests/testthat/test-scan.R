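test_that("exact HWE test matches a full-enumeration oracle", {
  # oracle: enumerate heterozygote counts and sum probabilities directly
  hwe_oracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2; nA <- 2 * n0 + n1; nB <- 2 * n2 + n1
    if (nA == 0 || nB == 0) return(1)
    hs <- seq(min(nA, nB) %% 2, min(nA, nB), 2)
    pr <- vapply(hs, function(h) {
      exp(h * log(2) + lfactorial(n) - lfactorial((nA - h) / 2) -
            lfactorial(h) - lfactorial((nB - h) / 2) +
            lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
    }, 0)
    sum(pr[pr <= pr[match(n1, hs)] + 1e-15])
  }
  cases <- list(c(250, 500, 250), c(5, 20, 75), c(88, 10, 2),
                c(0, 10, 90), c(30, 30, 40))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  expect_gt(hwe_exact_test(250, 500, 250), 0.9)  # perfectly HWE counts
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)    # no heterozygotes
})

test_that("genotype QC drops on per-stratum MAF, call rate and HWE", {
  set.seed(10)
  n <- 400
  strata <- rep(c("case", "control"), each = n / 2)
  g_ok <- rbinom(n, 2, 0.3)
  g_maf <- c(rbinom(n / 2, 2, 0.06), rbinom(n / 2, 2, 0.04))  # 4% in controls
  while (min(mean(g_maf[strata == "control"]) / 2,
             1 - mean(g_maf[strata == "control"]) / 2) >= 0.05 ||
         min(mean(g_maf[strata == "case"]) / 2,
             1 - mean(g_maf[strata == "case"]) / 2) < 0.05)
    g_maf <- c(rbinom(n / 2, 2, 0.06), rbinom(n / 2, 2, 0.04))
  g_call <- g_ok; g_call[sample(n, ceiling(0.11 * n))] <- NA  # 89% call rate
  g_hwe <- rep(c(0L, 2L), 200)   # MAF 0.5 everywhere, no heterozygotes
  codes <- cbind(ok = g_ok, low_maf = g_maf, low_call = g_call, hwe = g_hwe)
  rownames(codes) <- sprintf("s%03d", 1:n)
  info <- data.frame(snp_id = colnames(codes), chrom = "chr1", pos = 1:4,
                     ref = "A", alt = "C")
  G <- structure(list(codes = codes, info = info), class = "genotype_matrix")
  qc <- genotype_qc(G, strata = strata)
  expect_equal(qc$kept, "ok")
  st <- setNames(qc$report$status, qc$report$snp_id)
  expect_equal(unname(st["low_maf"]), "maf")
  expect_equal(unname(st["low_call"]), "call_rate")
  expect_equal(unname(st["hwe"]), "hwe")
  expect_error(genotype_qc(G, strata = rep("case", n - 1)), "strata")
})

test_that("platform merging drops discordant SNPs and blanks discordant calls", {
  mk <- function(codes, ids = sprintf("s%04d", seq_len(nrow(codes))),
                 ref = "A", alt = "C") {
    colnames(codes) <- sprintf("m%d", seq_len(ncol(codes)))
    rownames(codes) <- ids
    structure(list(codes = codes,
                   info = data.frame(snp_id = colnames(codes), chrom = "chr1",
                                     pos = seq_len(ncol(codes)), ref = ref,
                                     alt = alt)), class = "genotype_matrix")
  }
  set.seed(11)
  base <- matrix(rbinom(1000 * 2, 2, 0.3), 1000, 2)
  g2 <- base
  g2[1:10, 1] <- (base[1:10, 1] + 1L) %% 3L  # 1% discordant on SNP 1
  g2[1:2, 2] <- (base[1:2, 2] + 1L) %% 3L    # 0.2% discordant on SNP 2
  G1 <- mk(base); G2 <- mk(g2)
  M <- merge_platforms(G1, G2)
  expect_equal(attr(M, "dropped_discordant"), "m1")
  expect_false("m1" %in% colnames(M$codes))
  expect_true(all(is.na(M$codes[1:2, "m2"])))
  expect_equal(M$codes[3:1000, "m2"], base[3:1000, 2],
               ignore_attr = TRUE)
  # identity merge
  Mi <- merge_platforms(G1, G1)
  expect_identical(Mi$codes[, colnames(G1$codes)], G1$codes)
  # swapped alleles are recoded, non-complementary mismatches fail
  G2s <- mk(2L - base, ref = "C", alt = "A")
  Ms <- merge_platforms(G1, G2s)
  expect_identical(Ms$codes[, colnames(G1$codes)], G1$codes)
  G2bad <- mk(base, ref = "A", alt = "G")
  expect_error(merge_platforms(G1, G2bad), "unresolvable")
})

test_that("rare homozygotes collapse at the strict count threshold", {
  g <- c(rep(0L, 500), rep(1L, 300), rep(2L, 9))
  cr <- collapse_rare_homozygotes(g)
  expect_true(cr$collapsed)
  expect_equal(sum(cr$g == 1), 309)
  expect_false(any(cr$g == 2))
  g10 <- c(rep(0L, 500), rep(1L, 300), rep(2L, 10))
  cr10 <- collapse_rare_homozygotes(g10)
  expect_false(cr10$collapsed)
  expect_identical(cr10$g, g10)
  # symmetric rule and skip signal
  cr_sym <- collapse_rare_homozygotes(c(rep(0L, 5), rep(1L, 50), rep(2L, 50)))
  expect_true(cr_sym$collapsed && !cr_sym$skip)
  expect_true(collapse_rare_homozygotes(rep(1L, 100))$skip)
  expect_true(collapse_rare_homozygotes(c(rep(0L, 5), rep(2L, 5)))$skip)
})

test_that("pair classification is inclusive at exactly 1 Mb", {
  expect_equal(classify_pair("chr1", 1, "chr1", 1000001), "proximal")
  expect_equal(classify_pair("chr1", 1, "chr1", 1000002), "distal_same_chrom")
  expect_equal(classify_pair("chr1", 1, "chr2", 2), "distal_inter_chrom")
  expect_equal(classify_pair("chr1", c(1, 1), "chr1", c(5, 3e6)),
               c("proximal", "distal_same_chrom"))
  expect_error(classify_pair(NA, 1, "chr1", 1), "unknown chromosome")
})

test_that("fit_pair matches lm() and handles a perfect fit", {
  set.seed(12)
  y <- rbinom(100, 2, 0.4)
  perf <- fit_pair(y + 0, y, NULL)
  expect_equal(perf$r2, 1, tolerance = 1e-12)
  expect_lt(perf$p, 1e-100)
  # agreement with R's lm on a covariate model
  g <- rbinom(100, 2, 0.3)
  X <- data.frame(a = rnorm(100), b = factor(sample(letters[1:3], 100, TRUE)))
  yy <- 0.3 + 0.1 * g + 0.2 * X$a + rnorm(100, 0, 0.2)
  fp <- fit_pair(yy, g, X)
  m0 <- lm(yy ~ a + b, data = X)
  m1 <- lm(yy ~ a + b + g, data = cbind(X, g = g))
  expect_equal(fp$r2, 1 - sum(resid(m1)^2) / sum(resid(m0)^2),
               tolerance = 1e-10)
  expect_equal(fp$lrt, 100 * log(sum(resid(m0)^2) / sum(resid(m1)^2)),
               tolerance = 1e-10)
  expect_equal(fp$mean1, mean(yy[g == 1]))
  expect_error(fit_pair(yy[1:4], g[1:4], X[1:4, ]), "degrees of freedom")
})

test_that("fit_pair null p-values are uniform over repeated fits", {
  set.seed(13)
  p <- replicate(2000, {
    y <- rnorm(200)
    g <- rbinom(200, 2, 0.3)
    fit_pair(y, g)$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("scan conserves candidate counts and equals per-pair fits", {
  ch <- make_cohort(n_samples = 80, n_snps = 20, n_cpgs = 25, seed = 81)
  sc <- meqtl_scan(ch$beta, ch$G, ch$X, ch$map, mode = "all")
  expect_equal(sum(sc$counts), 20 * 25)
  expect_equal(nrow(sc$records), 20 * 25)
  # fast path equals fit_pair on a handful of random pairs
  set.seed(14)
  for (k in 1:10) {
    rec <- sc$records[sample(nrow(sc$records), 1), ]
    g <- collapse_rare_homozygotes(ch$G$codes[, rec$snp_id])$g
    fp <- fit_pair(ch$beta[, rec$cpg_id], g, ch$X)
    expect_equal(rec$p, fp$p, tolerance = 1e-10)
    expect_equal(rec$r2, fp$r2, tolerance = 1e-10)
    expect_equal(rec$mean1, fp$mean1, tolerance = 1e-12)
  }
  # missing-data path agrees with the complete-data fast path answers
  bm <- ch$beta
  bm[1, 1] <- NA
  scm <- meqtl_scan(bm, ch$G, ch$X, ch$map, mode = "proximal")
  prox <- sc$records[sc$records$class == "proximal", ]
  shared <- merge(scm$records, prox, by = c("snp_id", "cpg_id"))
  shared <- shared[shared$cpg_id != colnames(ch$beta)[1], ]
  expect_gt(nrow(shared), 0)
  expect_equal(shared$p.x, shared$p.y, tolerance = 1e-10)
})

test_that("scan modes restrict records but report full class counts", {
  ch <- make_cohort(n_samples = 60, n_snps = 10, n_cpgs = 12, seed = 91)
  sd <- meqtl_scan(ch$beta, ch$G, ch$X, ch$map, mode = "distal")
  expect_true(all(sd$records$class != "proximal"))
  expect_equal(sum(sd$counts), 10 * 12)
  expect_error(meqtl_scan(ch$beta[, , drop = FALSE] |>
                            `rownames<-`(paste0("x", 1:60)),
                          ch$G, ch$X, ch$map), "sample id mismatch")
})

test_that("BH step-up equals the sort-all oracle and p.adjust", {
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    f <- bh_fdr(p, q = 0.05)
    expect_identical(f$significant, bh_oracle(p, 0.05))
    expect_identical(f$significant, unname(p.adjust(p, "BH") <= 0.05))
  }
  one <- bh_fdr(0.04, q = 0.05)
  expect_true(one$significant)
  expect_equal(one$p_star, 0.04)
  none <- bh_fdr(rep(1, 10), q = 0.05)
  expect_equal(none$n_significant, 0)
  expect_error(bh_fdr(numeric(0), m = 0), "positive")
})

test_that("streaming BH over a p_cap tail equals full-sort BH", {
  set.seed(16)
  p <- c(runif(5000, 0.05, 1), runif(50, 0, 1e-6))
  full <- bh_fdr(p, q = 0.05)
  cap <- 1e-4
  tail_p <- p[p <= cap]
  streamed <- bh_fdr(tail_p, m = length(p), q = 0.05)
  expect_lt(full$p_star, cap)
  expect_equal(streamed$p_star, full$p_star)
  expect_equal(sum(streamed$significant), sum(full$significant))
})

test_that("stratified summary equals a brute-force tally with conserved margins", {
  ch <- make_cohort(n_samples = 150, n_snps = 30, n_cpgs = 50,
                    n_distal = 8, r = 0.25, seed = 101)
  sc <- meqtl_scan(ch$beta, ch$G, ch$X, ch$map, mode = "distal")
  fd <- scan_fdr(sc, "distal")
  vp <- variability_profile(ch$beta)
  sm <- summarize_counts(fd$records, vp)
  expect_equal(sum(sm$table), sm$total)
  expect_equal(sum(rowSums(sm$table)), length(unique(fd$records$cpg_id)))
  # brute-force tally oracle
  rec <- fd$records
  tally <- new.env()
  for (cg in unique(rec$cpg_id)) {
    rr <- rec[rec$cpg_id == cg, ]
    best <- rr$r2[which.max(rr$r2)]
    qx <- as.character(vp$quintile[vp$cpg_id == cg])
    labs <- c("<2%", "2-5%", "5-10%", "10-25%", "25-50%", "50-75%", "75%+")
    bin <- labs[findInterval(best, c(0.02, 0.05, 0.10, 0.25, 0.50, 0.75)) + 1]
    key <- paste(qx, bin)
    assign(key, (if (exists(key, tally)) get(key, tally) else 0) + 1, tally)
  }
  for (key in ls(tally)) {
    parts <- strsplit(key, " ")[[1]]
    expect_equal(unname(sm$table[parts[1], parts[2]]), get(key, tally))
  }
})

test_that("stratum concordance handles identity, disjoint and split cohorts", {
  expect_equal(stratum_concordance(c("a", "b"), c("a", "b")), 1)
  expect_equal(stratum_concordance(c("a", "b"), c("c")), 0)
  expect_error(stratum_concordance(character(), character()), "empty")
  # two half-cohorts sharing strongly planted truth overlap in discoveries
  map <- make_genome_map(2, 5e6, 40, 50, 1, seed = 111)
  G <- simulate_genotypes(map, 800, c(0.2, 0.5), 0, seed = 112)
  truth <- make_truth_table(map, n_distal = 6, r = 0.12, seed = 113)
  beta <- simulate_methylation(map, G, truth, NULL, seed = 114)
  half <- list(1:400, 401:800)
  sigs <- lapply(half, function(idx) {
    Gh <- structure(list(codes = G$codes[idx, ], info = G$info),
                    class = "genotype_matrix")
    sc <- meqtl_scan(beta[idx, ], Gh, NULL, map, mode = "distal")
    fd <- scan_fdr(sc, "distal")
    paste(fd$records$snp_id, fd$records$cpg_id)
  })
  expect_gt(stratum_concordance(sigs[[1]], sigs[[2]]), 0.5)
})

test_that("phenotype confound check is null for permuted status and hot for a real one", {
  set.seed(17)
  ch <- make_cohort(n_samples = 200, n_snps = 5, n_cpgs = 60, seed = 121)
  status <- sample(rep(c("case", "control"), each = 100))
  chk <- phenotype_confound_check(ch$beta, status, ch$X[, c("sex", "age")])
  expect_lt(chk$fraction, 0.05)
  expect_equal(chk$fraction, chk$n_significant / ncol(ch$beta))
  # status driving some sites is detected
  b2 <- ch$beta
  b2[, 1:10] <- plogis(qlogis(b2[, 1:10]) +
                         2 * (status == "case"))
  chk2 <- phenotype_confound_check(b2, status, ch$X[, c("sex", "age")])
  expect_gte(chk2$n_significant, 10)
  expect_error(phenotype_confound_check(ch$beta, rep("case", 200), NULL),
               "two classes")
})
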