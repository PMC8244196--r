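# Independent oracles used to verify the package implementations. These
# are deliberately naive: exhaustive enumeration and direct formula
# application, never sharing code with the implementation under test.

# build an undirected simple graph from a flat vector c("A","B", "B","C")
mk_g <- function(edges, isolated = character(0)) {
  nodes <- sort(unique(c(edges, isolated)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

# betweenness by explicit enumeration of all geodesics per unordered pair
naive_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  n <- length(nodes)
  if (n < 3) return(btw)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, nodes[i], nodes[j])$vpaths)
      if (!length(paths)) next
      w <- 1 / length(paths)
      for (p in paths) {
        inner <- igraph::as_ids(p)
        inner <- inner[-c(1, length(inner))]
        if (length(inner)) btw[inner] <- btw[inner] + w
      }
    }
  }
  btw
}

# Benjamini-Hochberg step-up by direct definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ranked[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by exhaustive enumeration of all draws
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "successes"
  mean(hits >= k)
}

# optimal K-exception subnetwork by enumeration of ALL node subsets
naive_best_subnetwork <- function(g, ind, K) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  best <- list(de = 0L, nodes = character(0))
  for (mask in seq_len(2^n - 1)) {
    sel <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    exc <- sum(ind[sel] == 0)
    if (exc > K) next
    de <- length(sel) - exc
    if (de < best$de) next
    if (!igraph::is_connected(igraph::induced_subgraph(g, sel))) next
    if (de > best$de) best <- list(de = de, nodes = sort(sel))
  }
  best
}

# all set partitions of a vector (Bell numbers; fine up to 8 elements)
all_partitions <- function(items) {
  if (length(items) == 0) return(list(list()))
  first <- items[1]
  rest <- all_partitions(items[-1])
  out <- list()
  for (part in rest) {
    for (b in seq_along(part)) {
      new <- part
      new[[b]] <- c(first, new[[b]])
      out[[length(out) + 1]] <- new
    }
    out[[length(out) + 1]] <- c(part, list(first))
  }
  out
}

# maximum modularity over all partitions (exhaustive, <= 8 nodes)
max_modularity <- function(g) {
  nodes <- igraph::V(g)$name
  stopifnot(length(nodes) <= 8)
  best <- -Inf
  for (part in all_partitions(nodes)) {
    memb <- integer(length(nodes))
    names(memb) <- nodes
    for (b in seq_along(part)) memb[part[[b]]] <- b
    q <- igraph::modularity(g, memb[igraph::V(g)$name])
    if (q > best) best <- q
  }
  best
}

# seeded Erdos-Renyi instance with a fixed fraction of indicator-1 nodes
random_instance <- function(n, p_edge, frac_one, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  ones <- sample(igraph::V(g)$name, max(1, round(frac_one * n)))
  ind <- stats::setNames(as.integer(igraph::V(g)$name %in% ones),
                         igraph::V(g)$name)
  list(g = g, ind = ind)
}

# small log2 expr_matrix from a matrix-like spec
mk_expr <- function(m, n_ctrl, n_trt, scale = "log2") {
  colnames(m) <- c(sprintf("c%d", seq_len(n_ctrl)), sprintf("t%d", seq_len(n_trt)))
  sheet <- data.frame(sample_id = colnames(m),
                      group = rep(c("control", "treatment"), c(n_ctrl, n_trt)))
  expr_matrix(m, scale, sheet)
}
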