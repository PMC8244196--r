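#' Jaccard index of two gene sets
#'
#' `J = |intersection| / |union|`, computed on the enriched (overlap) gene
#' sets of two pathways.
#'
#' @param g_i,g_j Character vectors of gene symbols; at least one
#'   non-empty.
#' @return J in `[0, 1]`.
#' @export
jaccard <- function(g_i, g_j) {
  g_i <- unique(g_i); g_j <- unique(g_j)
  u <- length(union(g_i, g_j))
  if (u == 0) stop("both gene sets empty")
  length(intersect(g_i, g_j)) / u
}

pairwise_jaccard <- function(sets) {
  terms <- names(sets)
  n <- length(terms)
  if (n < 2) {
    return(data.frame(term_i = character(0), term_j = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2)
  data.frame(
    term_i = terms[idx[1, ]], term_j = terms[idx[2, ]],
    jaccard = vapply(seq_len(ncol(idx)), function(c) {
      jaccard(sets[[idx[1, c]]], sets[[idx[2, c]]])
    }, numeric(1)), stringsAsFactors = FALSE)
}

#' Collapse redundant pathway terms
#'
#' Builds an auxiliary graph linking term pairs whose enriched-gene-set
#' Jaccard exceeds `redundancy_cutoff` (strict `>`), then keeps one
#' representative per connected component: smallest FDR, ties broken by
#' largest overlap size, then lexicographically smallest term.
#'
#' @param rows Filtered enrichment data frame (with `overlap_genes`).
#' @param redundancy_cutoff Strict Jaccard threshold (default 0.60).
#' @return List with `representatives` (subset of `rows`) and
#'   `redundancy_map` (data frame member -> representative, one row per
#'   input term).
#' @export
collapse_redundant <- function(rows, redundancy_cutoff = 0.60) {
  if (nrow(rows) == 0) {
    return(list(representatives = rows,
                redundancy_map = data.frame(member = character(0),
                                            representative = character(0),
                                            stringsAsFactors = FALSE)))
  }
  rows <- rows[order(rows$term), , drop = FALSE]
  sets <- overlap_sets(rows)
  pj <- pairwise_jaccard(sets)
  red <- pj[pj$jaccard > redundancy_cutoff, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(rows), name = rows$term)
  if (nrow(red)) g <- igraph::add_edges(g, rbind(red$term_i, red$term_j))
  comp <- igraph::components(g)
  membership <- comp$membership[rows$term]
  rep_of <- character(comp$no)
  for (ci in seq_len(comp$no)) {
    members <- rows[membership == ci, , drop = FALSE]
    o <- order(members$fdr, -members$k, members$term)
    rep_of[ci] <- members$term[o[1]]
  }
  reps <- rows[rows$term %in% rep_of, , drop = FALSE]
  rownames(reps) <- NULL
  list(representatives = reps,
       redundancy_map = data.frame(member = rows$term,
                                   representative = rep_of[membership],
                                   stringsAsFactors = FALSE))
}

#' Build the pathway-pathway crosstalk network
#'
#' Links representative pathway pairs sharing at least `crosstalk_cutoff`
#' of their enriched genes (Jaccard, inclusive `>=`); isolated terms are
#' kept as singleton nodes.
#'
#' @param representatives Data frame from [collapse_redundant()].
#' @param crosstalk_cutoff Inclusive Jaccard threshold (default 0.25).
#' @param redundancy_cutoff Recorded on the result (default 0.60).
#' @return Object of class `pathway_graph`: list with `nodes` (the
#'   enrichment rows), `edges` (term_i, term_j, jaccard), `graph`
#'   (igraph), the thresholds, and `clusters` (filled by
#'   [cluster_pathways()]).
#' @export
build_crosstalk_network <- function(representatives, crosstalk_cutoff = 0.25,
                                    redundancy_cutoff = 0.60) {
  rows <- representatives[order(representatives$term), , drop = FALSE]
  rownames(rows) <- NULL
  pj <- pairwise_jaccard(overlap_sets(rows))
  edges <- pj[pj$jaccard >= crosstalk_cutoff, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(rows), name = rows$term)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$term_i, edges$term_j))
    igraph::E(g)$weight <- edges$jaccard
  }
  structure(list(nodes = rows, edges = edges, graph = g,
                 clusters = NULL, crosstalk_cutoff = crosstalk_cutoff,
                 redundancy_cutoff = redundancy_cutoff),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d terms, %d crosstalk edges (J >= %.2f)",
              nrow(x$nodes), nrow(x$edges), x$crosstalk_cutoff))
  if (!is.null(x$clusters)) cat(sprintf(", %d clusters", length(unique(x$clusters))))
  cat("\n")
  invisible(x)
}

#' Cluster the pathway crosstalk network by greedy modularity
#'
#' Clauset-Newman-Moore greedy modularity agglomeration on the unweighted
#' crosstalk graph (set `weighted = TRUE` to use Jaccard edge weights).
#' Isolated nodes become singleton clusters. Cluster ids are relabelled
#' 1..n in order of each cluster's lexicographically smallest member so
#' the labelling is deterministic.
#'
#' @param pg A `pathway_graph`.
#' @param weighted Use Jaccard weights in the modularity (default FALSE).
#' @return The `pathway_graph` with `clusters` filled (named integer
#'   vector term -> cluster id).
#' @export
cluster_pathways <- function(pg, weighted = FALSE) {
  stopifnot(inherits(pg, "pathway_graph"))
  g <- pg$graph
  n <- igraph::vcount(g)
  if (n == 0) {
    pg$clusters <- stats::setNames(integer(0), character(0))
    return(pg)
  }
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(n)
  } else {
    w <- if (weighted) igraph::E(g)$weight else NULL
    cl <- igraph::cluster_fast_greedy(g, weights = w)
    memb <- igraph::membership(cl)
  }
  nm <- igraph::V(g)$name
  # deterministic relabelling by smallest member term
  first <- tapply(nm, memb, min)
  relabel <- stats::setNames(rank(first, ties.method = "first"), names(first))
  pg$clusters <- stats::setNames(as.integer(relabel[as.character(memb)]), nm)
  pg
}

#' Write pathway network tables
#'
#' @param pg A clustered `pathway_graph`.
#' @param redundancy_map Data frame from [collapse_redundant()].
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_clusters.tsv` and `<prefix>_redundancy.tsv`.
#' @export
write_pathway_network <- function(pg, redundancy_map, prefix) {
  utils::write.table(format_num(pg$edges, "jaccard"),
                     paste0(prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- data.frame(term = names(pg$clusters),
                   cluster = as.integer(pg$clusters),
                   stringsAsFactors = FALSE)
  utils::write.table(cl, paste0(prefix, "_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(redundancy_map, paste0(prefix, "_redundancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

# fixed-precision formatting so rewritten tables are byte-stable
format_num <- function(df, cols, digits = 10) {
  for (c in intersect(cols, names(df))) {
    df[[c]] <- formatC(df[[c]], digits = digits, format = "g")
  }
  df
}
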