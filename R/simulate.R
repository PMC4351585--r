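#' Simulate genotypes in Hardy-Weinberg equilibrium with block LD
#'
#' Draws two haplotypes per sample. Within an LD block all SNPs copy a
#' block-level latent haplotype indicator with a small flip probability
#' (`map$flip_prob`), which creates high within-block R2 and zero cross-block
#' R2; across haplotypes alleles are independent, so genotype counts follow
#' Hardy-Weinberg proportions at the realized allele frequency. Codes count
#' minor alleles (0/1/2), recoded against the empirical minor allele.
#'
#' @param map A [genome map][make_genome_map].
#' @param n_samples Number of samples.
#' @param maf_range Length-2 vector `(low, high)` with
#'   `0 <= low < high <= 0.5`; each block's target allele frequency is drawn
#'   uniformly from this range.
#' @param missing_rate Proportion of calls set to missing completely at
#'   random.
#' @param seed Integer seed.
#' @return An object of class `genotype_matrix`: list with `codes`
#'   (sample x SNP integer matrix, `NA` = missing) and `info` (data.frame
#'   `snp_id`, `chrom`, `pos`, `ref`, `alt`, `maf`, `call_rate`, `hwe_p`).
#' @examples
#' map <- make_genome_map(1, 1e6, 10, 10, 5, seed = 1)
#' G <- simulate_genotypes(map, 100, c(0.1, 0.5), 0, seed = 2)
#' table(G$codes[, 1])
#' @export
simulate_genotypes <- function(map, n_samples, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1L) {
  stopifnot(inherits(map, "genome_map"), n_samples >= 1,
            length(maf_range) == 2L,
            maf_range[1] >= 0, maf_range[1] < maf_range[2],
            maf_range[2] <= 0.5)
  stop_if_not_scalar_prop(missing_rate, "missing_rate")
  snps <- map$snps
  S <- nrow(snps)
  eps <- map$flip_prob
  with_seed(substream(seed, 1L), {
    codes <- matrix(0L, n_samples, S)
    for (b in unique(snps$block)) {
      idx <- which(snps$block == b)
      f <- stats::runif(1, maf_range[1], maf_range[2])
      e <- min(eps, f / 2)                 # keep latent frequency in (0,1)
      p <- (f - e) / (1 - 2 * e)
      # two latent haplotype indicators per sample, shared by the block
      h1 <- stats::rbinom(n_samples, 1L, p)
      h2 <- stats::rbinom(n_samples, 1L, p)
      for (j in idx) {
        a1 <- ifelse(stats::runif(n_samples) < e, 1L - h1, h1)
        a2 <- ifelse(stats::runif(n_samples) < e, 1L - h2, h2)
        codes[, j] <- a1 + a2
      }
    }
    # recode so that codes count the (empirical) minor allele
    freq <- colMeans(codes) / 2
    flip <- freq > 0.5
    codes[, flip] <- 2L - codes[, flip]
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_samples * S) < missing_rate, n_samples, S)
      codes[miss] <- NA_integer_
    }
    dimnames(codes) <- list(sprintf("s%04d", seq_len(n_samples)), snps$snp_id)
    info <- snps[, c("snp_id", "chrom", "pos", "ref", "alt")]
    info$counted_allele <- ifelse(flip, info$ref, info$alt)
    info$maf <- pmin(colMeans(codes, na.rm = TRUE) / 2,
                     1 - colMeans(codes, na.rm = TRUE) / 2)
    info$call_rate <- colMeans(!is.na(codes))
    info$hwe_p <- apply(codes, 2L, function(g) {
      n <- tabulate(g + 1L, nbins = 3L)
      hwe_exact_test(n[1L], n[2L], n[3L])
    })
    rownames(info) <- NULL
    structure(list(codes = codes, info = info), class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (MAF %.3f-%.3f)\n",
              nrow(x$codes), ncol(x$codes),
              min(x$info$maf), max(x$info$maf)))
  invisible(x)
}

#' Simulate a sample covariate table
#'
#' Sex, age, case/control status, batch (plate) and array position --- the
#' adjustment set the association model uses.
#'
#' @param n_samples Number of samples.
#' @param n_batches,n_positions Numbers of plate and array-position levels.
#' @param case_fraction Proportion of cases.
#' @param seed Integer seed.
#' @return data.frame with `sample_id`, `sex` ("F"/"M"), `age` (years),
#'   `status` ("case"/"control"), `batch`, `position` (factors).
#' @export
make_covariate_table <- function(n_samples, n_batches = 4L, n_positions = 12L,
                                 case_fraction = 0.5, seed = 1L) {
  with_seed(substream(seed, 2L), {
    data.frame(
      sample_id = sprintf("s%04d", seq_len(n_samples)),
      sex = sample(c("F", "M"), n_samples, replace = TRUE),
      age = round(stats::rnorm(n_samples, 64, 8), 1),
      status = ifelse(stats::runif(n_samples) < case_fraction,
                      "case", "control"),
      batch = factor(sample(paste0("b", seq_len(n_batches)), n_samples,
                            replace = TRUE)),
      position = factor(sample(paste0("p", seq_len(n_positions)), n_samples,
                               replace = TRUE)),
      stringsAsFactors = FALSE)
  })
}

#' Construct a ground-truth table for the methylation generator
#'
#' Chooses planted SNP-CpG effects (proximal and distal by the 1-Mb rule) of
#' specified latent partial R2, latent covariate coefficients, cell-type
#' latent profiles with a set of designated discriminating CpGs, and batch /
#' position offsets. The truth table is what power and false-discovery tests
#' are scored against.
#'
#' @param map A [genome map][make_genome_map].
#' @param n_proximal,n_distal Numbers of planted proximal / distal effects.
#' @param r Latent-scale partial R2 of each planted effect, recycled; values
#'   in (0,1).
#' @param n_cell_types Number of latent cell types.
#' @param n_discriminating Number of CpGs given large (>= 3 latent s.d.)
#'   between-cell-type separation, mirroring the 49 published
#'   blood-cell-discriminating sites.
#' @param covariate_effects Named latent coefficients for `sex`, `age`,
#'   `status`, `position`.
#' @param window Proximal window in bp.
#' @param seed Integer seed.
#' @return Object of class `truth_table`: list with `planted_effects`
#'   (data.frame `snp_id`, `cpg_id`, `r`, `sign`, `class`),
#'   `covariate_effects`, `cell_profiles` (cell type x CpG latent means),
#'   `batch_effects`, `position_effects`, `discriminating_sites`.
#' @export
make_truth_table <- function(map, n_proximal = 0L, n_distal = 0L, r = 0.1,
                             n_cell_types = 3L, n_discriminating = 49L,
                             covariate_effects = c(sex = 0.2, age = 0.005,
                                                   status = 0, position = 0.01),
                             window = 1e6, seed = 1L) {
  stopifnot(inherits(map, "genome_map"), all(r > 0), all(r < 1))
  n_eff <- n_proximal + n_distal
  r <- rep_len(r, max(n_eff, 1L))
  with_seed(substream(seed, 3L), {
    # sample candidate pairs and keep those of the requested distance class
    pick_pairs <- function(n, want_proximal) {
      out <- data.frame(snp_id = character(), cpg_id = character())
      guard <- 0L
      while (nrow(out) < n && guard < 200L) {
        guard <- guard + 1L
        s <- sample(nrow(map$snps), min(20L * n, nrow(map$snps)))
        g <- sample(nrow(map$cpgs), length(s), replace = TRUE)
        cl <- classify_pair(map$snps$chrom[s], map$snps$pos[s],
                            map$cpgs$chrom[g], map$cpgs$pos[g], window)
        keep <- if (want_proximal) cl == "proximal" else cl != "proximal"
        cand <- data.frame(snp_id = map$snps$snp_id[s][keep],
                           cpg_id = map$cpgs$cpg_id[g][keep],
                           stringsAsFactors = FALSE)
        out <- rbind(out, cand)
        out <- out[!duplicated(out$cpg_id), , drop = FALSE]
      }
      if (nrow(out) < n)
        stop("could not find enough pairs of the requested class")
      out[seq_len(n), , drop = FALSE]
    }
    planted <- NULL
    if (n_proximal > 0L) {
      pp <- pick_pairs(n_proximal, TRUE)
      pp$class <- "proximal"
      planted <- pp
    }
    if (n_distal > 0L) {
      pd <- pick_pairs(n_distal, FALSE)
      pd$class <- "distal"
      planted <- rbind(planted, pd)
      planted <- planted[!duplicated(planted$cpg_id), , drop = FALSE]
    }
    if (is.null(planted))
      planted <- data.frame(snp_id = character(), cpg_id = character(),
                            class = character(), stringsAsFactors = FALSE)
    planted$r <- r[seq_len(nrow(planted))]
    planted$sign <- sample(c(-1, 1), nrow(planted), replace = TRUE)

    n_cpg <- nrow(map$cpgs)
    profiles <- matrix(0, n_cell_types, n_cpg,
                       dimnames = list(paste0("cell", seq_len(n_cell_types)),
                                       map$cpgs$cpg_id))
    disc <- sample(map$cpgs$cpg_id, min(n_discriminating, n_cpg))
    # discriminating sites: wide between-cell-type latent separation
    profiles[, disc] <- stats::rnorm(n_cell_types * length(disc), 0, 4)
    other <- sample(setdiff(map$cpgs$cpg_id, disc),
                    round(0.1 * (n_cpg - length(disc))))
    profiles[, other] <- stats::rnorm(n_cell_types * length(other), 0, 0.5)

    structure(list(
      planted_effects = planted[, c("snp_id", "cpg_id", "r", "sign", "class")],
      covariate_effects = covariate_effects,
      cell_profiles = profiles,
      batch_effects = stats::rnorm(8L, 0, 0.3),
      position_effects = stats::rnorm(24L, 0, 0.1),
      discriminating_sites = disc), class = "truth_table")
  })
}

#' Simulate a methylation beta matrix with planted structure
#'
#' Builds a latent (logit-scale) value per sample and CpG:
#' `z = baseline + covariate effects + cell-mixture effect + batch/position
#' offsets + sum of planted SNP effects + Gaussian noise`, then maps it to
#' beta in (0,1) by the inverse logit. A planted effect with latent partial
#' R2 target `r` receives coefficient `b = sign * sqrt(r * sd^2 / ((1 - r) *
#' Var(g)))`, so that on the latent scale the genotype explains exactly `r`
#' of the residual variance in expectation. Cell composition is drawn from a
#' Dirichlet distribution per sample.
#'
#' The per-CpG baseline is a three-component mixture (hypo-, intermediate and
#' hyper-methylated) mimicking the bimodal shape of array methylation.
#'
#' @param map A [genome map][make_genome_map].
#' @param genotypes A `genotype_matrix` on the same map.
#' @param truth A [truth table][make_truth_table].
#' @param covariates Covariate table from [make_covariate_table()] (or `NULL`
#'   for none).
#' @param n_cell_types Number of cell types; must match `truth`.
#' @param noise_sd Latent-scale residual standard deviation.
#' @param seed Integer seed.
#' @return Sample x CpG matrix of beta values in (0,1), with the latent
#'   matrix attached as attribute `"latent"` and cell proportions as
#'   `"cell_proportions"`.
#' @export
simulate_methylation <- function(map, genotypes, truth, covariates = NULL,
                                 n_cell_types = 3L, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(map, "genome_map"), inherits(truth, "truth_table"),
            nrow(truth$cell_profiles) == n_cell_types)
  codes <- genotypes$codes
  n <- nrow(codes)
  cpg_ids <- map$cpgs$cpg_id
  C <- length(cpg_ids)
  pe <- truth$planted_effects
  if (nrow(pe) > 0L) {
    if (!all(pe$snp_id %in% colnames(codes)) ||
        !all(pe$cpg_id %in% cpg_ids))
      stop("truth table references unknown SNP or CpG ids")
  }
  with_seed(substream(seed, 4L), {
    base <- sample(c(-2.5, 0, 2.5), C, replace = TRUE,
                   prob = c(0.3, 0.4, 0.3)) + stats::rnorm(C, 0, 0.5)
    z <- matrix(rep(base, each = n), n, C)

    if (!is.null(covariates)) {
      ce <- truth$covariate_effects
      sx <- as.numeric(covariates$sex == "M") * ce[["sex"]]
      ag <- (covariates$age - mean(covariates$age)) * ce[["age"]]
      st <- as.numeric(covariates$status == "case") * ce[["status"]]
      ps <- as.integer(factor(covariates$position)) * ce[["position"]]
      bt <- truth$batch_effects[as.integer(factor(covariates$batch))]
      z <- z + (sx + ag + st + ps + bt)
    }

    # Dirichlet cell proportions (decreasing concentration: one dominant type)
    alpha <- 6 / seq_len(n_cell_types)
    gam <- matrix(stats::rgamma(n * n_cell_types, shape = rep(alpha, each = n)),
                  n, n_cell_types)
    props <- gam / rowSums(gam)
    z <- z + props %*% truth$cell_profiles[, cpg_ids, drop = FALSE]

    if (nrow(pe) > 0L) {
      info <- genotypes$info
      for (k in seq_len(nrow(pe))) {
        g <- codes[, pe$snp_id[k]]
        # planted effects attach to the ALT allele, so two cohorts with
        # different minor alleles still share the same biological direction
        ii <- match(pe$snp_id[k], info$snp_id)
        if (!is.null(info$counted_allele) &&
            info$counted_allele[ii] != info$alt[ii])
          g <- 2L - g
        vg <- stats::var(g, na.rm = TRUE)
        if (is.na(vg) || vg == 0)
          stop(sprintf("planted pair uses monomorphic SNP %s", pe$snp_id[k]))
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        b <- pe$sign[k] * sqrt(pe$r[k] * noise_sd^2 / ((1 - pe$r[k]) * vg))
        j <- match(pe$cpg_id[k], cpg_ids)
        z[, j] <- z[, j] + b * (g - mean(g))
      }
    }
    z <- z + matrix(stats::rnorm(n * C, 0, noise_sd), n, C)
    beta <- inv_logit(z)
    dimnames(beta) <- list(rownames(codes), cpg_ids)
    dimnames(z) <- dimnames(beta)
    attr(beta, "latent") <- z
    attr(beta, "cell_proportions") <- props
    beta
  })
}

#' Simulate methylated/unmethylated intensity pairs with detection scores
#'
#' Inverts the beta computation: `M = beta * T`, `U = (1 - beta) * T`, each
#' multiplied by mean-one lognormal noise with coefficient of variation
#' `noise_cv`, so that `E[M / (M + U)]` is approximately `beta`. Detection
#' scores use the confidence convention (high = reliably above background): a
#' `detection_fail_rate` fraction of entries receive scores below 0.01 and
#' are masked by the default settings of [mask_detection()].
#'
#' @param beta Sample x CpG beta matrix.
#' @param total_intensity Expected total signal `M + U` per entry.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param detection_fail_rate Proportion of entries failing detection.
#' @param seed Integer seed.
#' @return List with matrices `M`, `U`, `detection` (all sample x CpG).
#' @export
simulate_intensities <- function(beta, total_intensity = 5000, noise_cv = 0.05,
                                 detection_fail_rate = 0, seed = 1L) {
  stopifnot(total_intensity > 0)
  stop_if_not_scalar_prop(detection_fail_rate, "detection_fail_rate")
  n <- length(beta)
  with_seed(substream(seed, 5L), {
    noise <- function() {
      if (noise_cv == 0) return(1)
      sdl <- sqrt(log(1 + noise_cv^2))
      matrix(stats::rlnorm(n, -sdl^2 / 2, sdl), nrow(beta), ncol(beta))
    }
    M <- beta * total_intensity * noise()
    U <- (1 - beta) * total_intensity * noise()
    det <- matrix(stats::runif(n, 0.01, 1), nrow(beta), ncol(beta))
    if (detection_fail_rate > 0) {
      fail <- matrix(stats::runif(n) < detection_fail_rate,
                     nrow(beta), ncol(beta))
      det[fail] <- stats::runif(sum(fail), 0, 0.0099)
    }
    dimnames(M) <- dimnames(U) <- dimnames(det) <- dimnames(beta)
    list(M = M, U = U, detection = det)
  })
}

#' Simulate BED-like feature tracks with controllable enrichment
#'
#' Places features of one or more classes on the genome. Inside
#' `enriched_regions`, the expected feature start density is
#' `enrichment_factor` times the background density; elsewhere it is uniform.
#' This gives downstream [enrichment_test()] a knob whose true fold is known.
#'
#' @param map A [genome map][make_genome_map].
#' @param n_features_per_class Named integer vector, e.g.
#'   `c(gene = 200, piRNA = 100)`.
#' @param enriched_regions data.frame `chrom`, `start`, `end` (1-based,
#'   inclusive) or `NULL`.
#' @param enrichment_factor Fold enrichment of feature density inside the
#'   regions; must be >= 1.
#' @param width_range Feature widths are drawn log-uniformly from this range
#'   (bp).
#' @param seed Integer seed.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), `name`,
#'   `class`, `strand`.
#' @export
make_feature_tracks <- function(map, n_features_per_class, enriched_regions,
                                enrichment_factor = 1,
                                width_range = c(500, 20000), seed = 1L) {
  stopifnot(inherits(map, "genome_map"), enrichment_factor >= 1)
  has_regions <- !is.null(enriched_regions) && nrow(enriched_regions) > 0L
  if (!has_regions && enrichment_factor > 1)
    stop("enrichment_factor > 1 requires a non-empty region list")
  chroms <- map$chromosomes
  with_seed(substream(seed, 6L), {
    # per-chromosome enriched spans (merged so lengths are exact)
    enr <- if (has_regions) merge_regions(enriched_regions)$regions else NULL
    out <- vector("list", length(n_features_per_class))
    for (ci in seq_along(n_features_per_class)) {
      cls <- names(n_features_per_class)[ci]
      nf <- n_features_per_class[[ci]]
      # chromosome + zone weights: outside length + factor * enriched length
      w_in <- vapply(chroms$chrom, function(ch) {
        if (is.null(enr)) return(0)
        e <- enr[enr$chrom == ch, , drop = FALSE]
        sum(e$end - e$start + 1)
      }, 0)
      w_out <- chroms$length - w_in
      w <- w_out + enrichment_factor * w_in
      chrom_i <- sample.int(nrow(chroms), nf, replace = TRUE, prob = w)
      start <- integer(nf)
      for (k in seq_len(nf)) {
        ch <- chrom_i[k]
        inside <- stats::runif(1) <
          enrichment_factor * w_in[ch] / w[ch]
        if (inside) {
          e <- enr[enr$chrom == chroms$chrom[ch], , drop = FALSE]
          lens <- e$end - e$start + 1
          r <- sample.int(nrow(e), 1L, prob = lens)
          start[k] <- e$start[r] + sample.int(lens[r], 1L) - 1L
        } else {
          repeat {
            cand <- sample.int(chroms$length[ch], 1L)
            if (is.null(enr)) break
            e <- enr[enr$chrom == chroms$chrom[ch], , drop = FALSE]
            if (nrow(e) == 0L || !any(cand >= e$start & cand <= e$end)) break
          }
          start[k] <- cand
        }
      }
      wdt <- round(exp(stats::runif(nf, log(width_range[1]),
                                    log(width_range[2]))))
      end <- pmin(start + wdt - 1, chroms$length[chrom_i])
      out[[ci]] <- data.frame(
        chrom = chroms$chrom[chrom_i], start = start, end = end,
        name = sprintf("%s_%05d", cls, seq_len(nf)), class = cls,
        strand = sample(c("+", "-"), nf, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
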