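# Shared fixture builder: a small synthetic cohort with optional planted
# effects. ld_block_size = 1 gives independent SNPs, which calibration
# fixtures use so that truth-table scoring is unambiguous.
make_cohort <- function(n_samples = 200, n_snps = 50, n_cpgs = 60,
                        n_chrom = 2, chrom_length = 5e6, ld_block_size = 1,
                        n_proximal = 0, n_distal = 0, r = 0.1,
                        maf_range = c(0.1, 0.5), noise_sd = 1, seed = 1) {
  map <- make_genome_map(n_chrom, chrom_length, n_snps, n_cpgs,
                         ld_block_size, seed = seed)
  G <- simulate_genotypes(map, n_samples, maf_range, 0, seed = seed + 1)
  cov <- make_covariate_table(n_samples, seed = seed + 2)
  truth <- make_truth_table(map, n_proximal = n_proximal, n_distal = n_distal,
                            r = r, seed = seed + 3)
  beta <- simulate_methylation(map, G, truth, cov, noise_sd = noise_sd,
                               seed = seed + 4)
  X <- data.frame(sex = cov$sex, age = cov$age, status = cov$status,
                  batch = cov$batch)
  list(map = map, G = G, cov = cov, truth = truth, beta = beta, X = X)
}

# Independent OLS oracle: fits null and full models by explicit normal
# equations and returns the same quantities as fit_pair().
normal_equations_oracle <- function(y, g, X0) {
  # X0: design matrix including intercept (no genotype column)
  bt0 <- solve(t(X0) %*% X0, t(X0) %*% y)
  r0 <- y - X0 %*% bt0
  X1 <- cbind(X0, g)
  bt1 <- solve(t(X1) %*% X1, t(X1) %*% y)
  r1 <- y - X1 %*% bt1
  rss0 <- sum(r0^2); rss1 <- sum(r1^2)
  n <- length(y)
  lrt <- n * log(rss0 / rss1)
  list(lrt = lrt, p = pchisq(lrt, 1, lower.tail = FALSE),
       r2 = 1 - rss1 / rss0)
}

# Independent BFS oracle over an adjacency list (no igraph).
bfs_dist <- function(adj, from, to) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (dist[w] == Inf) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist[to]
}

# Sort-based BH oracle over the full p-value list.
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  ok <- which(sp <= q * seq_len(m) / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= sp[max(ok)]
}
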