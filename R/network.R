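#' Build a simple undirected interaction graph
#'
#' @param edges data.frame (or two-column matrix) of gene-symbol pairs.
#' @return An undirected, simplified `igraph` graph (no self-loops or
#'   multi-edges).
#' @export
interaction_graph <- function(edges) {
  g <- igraph::graph_from_data_frame(as.data.frame(edges)[, 1:2],
                                     directed = FALSE)
  igraph::simplify(g)
}

#' Mean shortest path between gene pairs on an interaction network
#'
#' Projects SNP-annotated / CpG-annotated gene pairs onto the interaction
#' graph and averages their shortest-path (BFS) distances. Pairs with either
#' gene unmapped, or with the two genes in different connected components,
#' are excluded and counted. Pairs at distance 1 are reported as direct
#' interactions.
#'
#' @param pairs data.frame with two character columns (`gene_a`, `gene_b`).
#' @param graph An `igraph` graph (see [interaction_graph()]).
#' @return List: `mean` (mean distance over usable pairs), `n_usable`,
#'   `n_excluded`, `distances` (per usable pair), `direct` (data.frame of
#'   distance-1 pairs), `usable` (logical over input pairs).
#' @export
mean_shortest_path <- function(pairs, graph) {
  vs <- igraph::V(graph)$name
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  comp <- igraph::components(graph)$membership
  mapped <- a %in% vs & b %in% vs
  usable <- mapped
  usable[mapped] <- comp[a[mapped]] == comp[b[mapped]]
  if (!any(usable)) stop("no usable pairs (unmapped or disconnected)")
  ua <- a[usable]; ub <- b[usable]
  D <- igraph::distances(graph, v = unique(ua), to = unique(ub))
  d <- D[cbind(match(ua, rownames(D)), match(ub, colnames(D)))]
  direct <- data.frame(gene_a = ua[d == 1], gene_b = ub[d == 1],
                       stringsAsFactors = FALSE)
  list(mean = mean(d), n_usable = sum(usable),
       n_excluded = sum(!usable), distances = d, direct = direct,
       usable = usable)
}

#' Null distribution of the mean shortest path
#'
#' Repeatedly samples `n_pairs` uniform random connected gene pairs (two
#' distinct vertices of the same component, components weighted by their
#' number of pairs) and records the mean shortest-path distance of each
#' replicate. The one-sided p-value is the proportion of replicate means
#' less than or equal to the observed mean (are the observed pairs *closer*
#' than random?); a two-sided version doubles the smaller tail.
#'
#' @param graph An `igraph` graph.
#' @param n_pairs Pairs per replicate (match the observed usable count).
#' @param R Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param observed_mean Observed mean distance to score against the null.
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return List: `null_means` (length `R`), `mean` (their average), `p`,
#'   `p_label` (`"< 1/R"` when no replicate is as extreme).
#' @export
null_shortest_path <- function(graph, n_pairs, R = 1000L, seed = 1L,
                               observed_mean,
                               alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (R < 1L) stop("R must be at least 1")
  comp <- igraph::components(graph)
  sizes <- comp$csize
  n_conn_pairs <- sum(sizes * (sizes - 1) / 2)
  if (n_conn_pairs < n_pairs)
    stop("graph has fewer connectable pairs than n_pairs")
  members <- split(igraph::V(graph)$name, comp$membership)
  w <- sizes * (sizes - 1) / 2
  null_means <- with_seed(substream(seed, 8L), {
    vapply(seq_len(R), function(r) {
      ci <- sample.int(length(sizes), n_pairs, replace = TRUE, prob = w)
      a <- character(n_pairs); b <- character(n_pairs)
      for (k in seq_len(n_pairs)) {
        v <- sample(members[[ci[k]]], 2L)
        a[k] <- v[1L]; b[k] <- v[2L]
      }
      D <- igraph::distances(graph, v = unique(a), to = unique(b))
      mean(D[cbind(match(a, rownames(D)), match(b, colnames(D)))])
    }, 0)
  })
  k <- sum(null_means <= observed_mean)
  p <- switch(alternative,
              less = k / R,
              two.sided = min(1, 2 * min(k, R - k) / R))
  list(null_means = null_means, mean = mean(null_means), p = p,
       p_label = if (p == 0) paste0("< 1/", R) else format(p, digits = 3))
}
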