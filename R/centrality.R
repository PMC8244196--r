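#' Degree and betweenness centrality of a subnetwork
#'
#' Degree is the induced-subgraph adjacency count. Betweenness is the
#' classic shortest-path betweenness (Brandes accumulation): unweighted
#' geodesics, endpoints excluded, fractional credit across equally short
#' paths, reported per unordered source-target pair and unnormalized.
#'
#' @param sol A non-empty `subnetwork_solution`, or any igraph graph.
#' @param normalized Divide betweenness by `(n-1)(n-2)/2` (default FALSE,
#'   raw scores).
#' @return Data frame with columns `gene`, `degree`, `betweenness`,
#'   ordered by gene symbol.
#' @export
compute_centrality <- function(sol, normalized = FALSE) {
  g <- if (inherits(sol, "subnetwork_solution")) {
    if (!length(sol$nodes)) stop("empty subnetwork")
    sg <- igraph::make_empty_graph(n = 0, directed = FALSE)
    sg <- igraph::add_vertices(sg, length(sol$nodes), name = sol$nodes)
    if (nrow(sol$edges)) {
      sg <- igraph::add_edges(sg, rbind(sol$edges$a, sol$edges$b))
    }
    sg
  } else sol
  if (igraph::vcount(g) == 0) stop("empty subnetwork")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  out <- data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
                    betweenness = as.numeric(btw), stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Select top hub genes by combined degree/betweenness rank
#'
#' Each gene is ranked descending under betweenness and under degree (ties
#' share the mean rank); the composite rank is the average of the two.
#' The top `n` genes by composite rank are returned, final ties broken
#' lexicographically.
#'
#' @param centrality Data frame from [compute_centrality()].
#' @param n Number of hub genes (default 5, as in top-5 hub reporting).
#' @return Data frame with per-metric ranks, `composite_rank` (position
#'   1..n of the ordering) and `top_n_flag`; rows ordered by the composite
#'   ordering.
#' @export
top_genes <- function(centrality, n = 5) {
  stopifnot(n >= 1)
  if (n > nrow(centrality)) {
    warning("n exceeds table size; returning all ", nrow(centrality), " genes")
    n <- nrow(centrality)
  }
  rank_btw <- rank(-centrality$betweenness, ties.method = "average")
  rank_deg <- rank(-centrality$degree, ties.method = "average")
  composite <- (rank_btw + rank_deg) / 2
  ord <- order(composite, centrality$gene)
  out <- centrality[ord, , drop = FALSE]
  out$rank_betweenness <- rank_btw[ord]
  out$rank_degree <- rank_deg[ord]
  out$composite_score <- composite[ord]
  out$composite_rank <- seq_len(nrow(out))
  out$top_n_flag <- as.integer(out$composite_rank <= n)
  rownames(out) <- NULL
  out
}
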