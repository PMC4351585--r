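#' 95% reference range of a methylation site
#'
#' The difference between the 97.5th and 2.5th percentiles of a CpG's beta
#' values across samples (more generally, the central `coverage` fraction):
#' the inter-individual variability metric used to select sites for PCA and
#' to stratify scan results into quintiles. Percentiles use the
#' linear-interpolation definition (`stats::quantile` type 7); missing values
#' are excluded.
#'
#' @param values Numeric vector of beta values for one CpG.
#' @param coverage Central coverage (default 0.95).
#' @return The reference range, in beta units.
#' @examples
#' reference_range(seq(0, 1, length.out = 21))
#' @export
reference_range <- function(values, coverage = 0.95) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) stop("need at least 2 non-missing values")
  a <- (1 - coverage) / 2
  q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  q[2L] - q[1L]
}

#' Per-CpG variability profile with quintile strata
#'
#' Computes the 95% reference range of every CpG and assigns balanced
#' variability quintiles Q1 (least variable) to Q5 (most variable). Quintile
#' sizes differ by at most one site; ties in the range are broken by CpG id
#' order.
#'
#' @param beta Sample x CpG beta matrix.
#' @param n_strata Number of strata (default 5).
#' @param coverage Passed to [reference_range()].
#' @return Object of class `variability_profile`: data.frame `cpg_id`,
#'   `ref_range`, `quintile` (factor Q1..Qn), with attribute `"boundaries"`
#'   (range values at the stratum edges).
#' @export
variability_profile <- function(beta, n_strata = 5L, coverage = 0.95) {
  rr <- apply(beta, 2L, reference_range, coverage = coverage)
  ids <- colnames(beta)
  ord <- order(rr, ids)                       # ties broken by CpG id
  m <- length(rr)
  sizes <- rep(m %/% n_strata, n_strata) +
    (seq_len(n_strata) <= m %% n_strata)
  q <- integer(m)
  q[ord] <- rep(seq_len(n_strata), times = sizes)
  bounds <- vapply(seq_len(n_strata - 1L),
                   function(k) max(rr[q == k]), 0)
  out <- data.frame(cpg_id = ids, ref_range = rr,
                    quintile = factor(paste0("Q", q),
                                      levels = paste0("Q", seq_len(n_strata))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "boundaries") <- bounds
  class(out) <- c("variability_profile", class(out))
  out
}

# Principal components of the sample-by-sample covariance matrix computed
# across a set of sites (each site centered; pairwise-complete when values
# are missing). Returns sample scores scaled by the singular values, site
# loadings, and per-component variance fractions.
pca_over_sites <- function(mat, n_components) {
  # mat: samples x sites
  X <- t(mat)                                  # sites x samples
  X <- X - rowMeans(X, na.rm = TRUE)           # center each site
  m <- nrow(X)
  if (anyNA(X)) {
    X0 <- X
    X0[is.na(X0)] <- 0
    N <- crossprod(!is.na(X))                  # complete pairs per cell
    C <- crossprod(X0) / pmax(N - 1, 1)
  } else {
    C <- crossprod(X) / (m - 1)
  }
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  # at most min(samples, sites) informative components
  vals <- vals[seq_len(min(length(vals), m))]
  k <- min(n_components, sum(vals > 0))
  d <- sqrt(vals[seq_len(k)] * (m - 1))
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(d, k)
  rownames(scores) <- colnames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  X0 <- X
  X0[is.na(X0)] <- 0
  loadings <- X0 %*% e$vectors[, seq_len(k), drop = FALSE] %*% diag(1 / d, k)
  rownames(loadings) <- rownames(X)
  colnames(loadings) <- colnames(scores)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = vals / sum(vals)),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("pc_result: %d samples, %d component(s); variance explained: %s\n",
              nrow(x$scores), k,
              paste(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Principal components over the most variable sites
#'
#' Eigen-decomposition of the sample-by-sample covariance matrix computed
#' over the autosomal CpG sites whose 95% reference range is at least
#' `min_range`. These global components are used for sample outlier
#' exclusion and for sensitivity analyses adjusting for hidden confounders.
#' Missing values are handled by pairwise-complete covariance.
#'
#' @param beta Sample x CpG beta matrix.
#' @param min_range Minimum 95% reference range for a site to enter the
#'   covariance computation (default 0.20).
#' @param n_components Number of components to return.
#' @return Object of class `pc_result`: `scores` (sample x component),
#'   `loadings` (site x component), `variance_explained` (all components).
#' @export
variance_pca <- function(beta, min_range = 0.20, n_components = 12L) {
  rr <- apply(beta, 2L, reference_range)
  pass <- which(rr >= min_range)
  if (length(pass) == 0L) stop("no sites pass the reference-range filter")
  if (length(pass) < n_components)
    n_components <- length(pass)
  pca_over_sites(beta[, pass, drop = FALSE], n_components)
}

#' Cell-composition surrogate principal components
#'
#' PCA restricted to a published list of CpG sites that discriminate between
#' blood cell types; the leading components serve as a surrogate for
#' cell-type proportions in the association model. The variance explained by
#' the returned components is reported so it can be checked against the
#' expectation that the top two capture most (>90%) of the variance at
#' these sites.
#'
#' @param beta Sample x CpG beta matrix.
#' @param discriminating_sites Character vector of CpG ids (the stand-in for
#'   the published 49-site list).
#' @param n_components Number of surrogate components (default 2).
#' @return Object of class `pc_result`.
#' @export
cell_surrogate <- function(beta, discriminating_sites, n_components = 2L) {
  sites <- intersect(discriminating_sites, colnames(beta))
  if (length(sites) < 2L)
    stop("fewer than 2 discriminating sites found in the matrix")
  pca_over_sites(beta[, sites, drop = FALSE], n_components)
}
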