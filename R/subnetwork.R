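# K-exception active-subnetwork extraction: find a connected subgraph of
# the interactome maximizing the number of differentially expressed
# (indicator-1) genes while containing at most K indicator-0 "exception"
# nodes. The greedy solver seeds a candidate at every indicator-1 node and
# grows it; the exact solver enumerates exception subsets and is the
# provable optimum on small graphs.

normalize_indicator <- function(g, ind) {
  nodes <- igraph::V(g)$name
  out <- stats::setNames(integer(length(nodes)), nodes)
  if (length(ind)) {
    names(ind) <- toupper(trimws(names(ind)))
    hit <- intersect(nodes, names(ind)[ind == 1])
    out[hit] <- 1L
  }
  out
}

induced_edges <- function(g, nodes) {
  sg <- igraph::induced_subgraph(g, nodes)
  el <- igraph::as_edgelist(sg)
  if (nrow(el) == 0) {
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  }
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  o <- order(lo, hi)
  data.frame(a = lo[o], b = hi[o], stringsAsFactors = FALSE)
}

new_subnetwork_solution <- function(g, nodes, ind, K, variant) {
  nodes <- sort(nodes)
  exceptions <- sort(nodes[ind[nodes] == 0])
  sol <- structure(list(
    nodes = nodes,
    edges = induced_edges(g, nodes),
    exceptions = exceptions,
    de_count = length(nodes) - length(exceptions),
    K = K, variant = variant), class = "subnetwork_solution")
  # invariants asserted on every emitted solution
  if (length(nodes)) {
    stopifnot(length(exceptions) <= K, sol$de_count >= 1)
    sg <- igraph::induced_subgraph(g, nodes)
    stopifnot(igraph::is_connected(sg))
  }
  sol
}

empty_solution <- function(K, variant) {
  structure(list(nodes = character(0),
                 edges = data.frame(a = character(0), b = character(0),
                                    stringsAsFactors = FALSE),
                 exceptions = character(0), de_count = 0L, K = K,
                 variant = variant), class = "subnetwork_solution")
}

#' @export
print.subnetwork_solution <- function(x, ...) {
  cat(sprintf("subnetwork_solution (%s): %d nodes, %d edges, %d DE genes, %d exception(s) (K=%d)\n",
              x$variant, length(x$nodes), nrow(x$edges), x$de_count,
              length(x$exceptions), x$K))
  invisible(x)
}

# prefer larger de_count, then fewer exceptions, then smallest node list
solution_better <- function(cand, best) {
  if (is.null(best)) return(TRUE)
  if (cand$de_count != best$de_count) return(cand$de_count > best$de_count)
  if (length(cand$exceptions) != length(best$exceptions)) {
    return(length(cand$exceptions) < length(best$exceptions))
  }
  a <- paste(cand$nodes, collapse = "\r")
  b <- paste(best$nodes, collapse = "\r")
  a < b
}

#' Greedy K-exception maximum subnetwork
#'
#' Seeds a candidate at every indicator-1 node (in lexicographic order)
#' and grows it: indicator-1 neighbours are always absorbed; an
#' indicator-0 neighbour is added only while exception budget remains and
#' only when it unlocks at least one new indicator-1 node, preferring the
#' exception unlocking the most (ties lexicographic). Growth stops when no
#' admissible addition exists; the best candidate is returned (largest DE
#' count, then fewest exceptions, then lexicographically smallest node
#' list). The result is locally maximal: no indicator-1 node adjacent to
#' it remains unadded.
#'
#' @param g igraph interactome.
#' @param ind Named 0/1 indicator vector; nodes absent default to 0.
#' @param K Maximum number of exception nodes (default 5).
#' @param variant Label recorded on the solution.
#' @return A `subnetwork_solution`.
#' @export
greedy_max_subnetwork <- function(g, ind, K = 5, variant = "all") {
  stopifnot(K >= 0)
  ind <- normalize_indicator(g, ind)
  ones <- sort(names(ind)[ind == 1])
  if (!length(ones)) {
    warning("no indicator-1 node in graph; returning empty solution")
    return(empty_solution(K, variant))
  }
  adj <- lapply(igraph::as_adj_list(g), function(v) sort(v$name))
  names(adj) <- igraph::V(g)$name

  # indicator-1 nodes reachable from `starts` walking over indicator-1
  # nodes only, excluding anything already in `in_s`
  ones_closure <- function(starts, in_s) {
    seen <- character(0)
    queue <- starts[ind[starts] == 1 & !(starts %in% in_s)]
    queue <- unique(queue)
    while (length(queue)) {
      x <- queue[[1]]; queue <- queue[-1]
      if (x %in% seen) next
      seen <- c(seen, x)
      nb <- adj[[x]]
      nb <- nb[ind[nb] == 1 & !(nb %in% in_s) & !(nb %in% seen)]
      queue <- c(queue, nb)
    }
    seen
  }

  grow <- function(seed) {
    S <- c(seed, ones_closure(adj[[seed]], seed))
    exc <- character(0)
    repeat {
      if (length(exc) >= K) break
      nb <- unique(unlist(adj[S], use.names = FALSE))
      nb0 <- sort(nb[!(nb %in% S) & ind[nb] == 0])
      if (!length(nb0)) break
      gains <- vapply(nb0, function(z) length(ones_closure(adj[[z]], S)),
                      integer(1))
      best <- max(gains)
      if (best < 1) break
      z <- nb0[which(gains == best)[1]]  # nb0 sorted -> lexicographic tie
      exc <- c(exc, z)
      S <- c(S, z, ones_closure(adj[[z]], S))
    }
    S
  }

  best <- NULL
  for (seed in ones) {
    S <- grow(seed)
    cand <- new_subnetwork_solution(g, S, ind, K, variant)
    if (solution_better(cand, best)) best <- cand
  }
  best
}

#' Exact K-exception maximum subnetwork (small graphs)
#'
#' Provably optimal solution by enumeration: every feasible solution is
#' contained in a connected component of the subgraph induced by the
#' indicator-1 nodes plus some exception set E with `|E| <= K`, so
#' enumerating all such E and scoring component DE counts covers the
#' optimum. Tie-breaking matches [greedy_max_subnetwork()]. Guarded to
#' graphs with at most 20 nodes.
#'
#' @inheritParams greedy_max_subnetwork
#' @return A `subnetwork_solution` with the optimal DE count.
#' @export
exact_max_subnetwork <- function(g, ind, K = 5, variant = "all") {
  stopifnot(K >= 0)
  n <- igraph::vcount(g)
  if (n > 20) stop("exact solver limited to graphs with <= 20 nodes (got ", n, ")")
  ind <- normalize_indicator(g, ind)
  ones <- names(ind)[ind == 1]
  if (!length(ones)) {
    warning("no indicator-1 node in graph; returning empty solution")
    return(empty_solution(K, variant))
  }
  zeros <- sort(names(ind)[ind == 0])
  best <- NULL
  consider <- function(E) {
    sg <- igraph::induced_subgraph(g, c(ones, E))
    comp <- igraph::components(sg)
    nm <- igraph::V(sg)$name
    for (ci in seq_len(comp$no)) {
      members <- nm[comp$membership == ci]
      if (!any(ind[members] == 1)) next
      cand <- new_subnetwork_solution(g, members, ind, K, variant)
      if (solution_better(cand, best)) best <<- cand
    }
  }
  consider(character(0))
  kmax <- min(K, length(zeros))
  if (kmax >= 1) {
    for (k in seq_len(kmax)) {
      idx <- utils::combn(length(zeros), k)
      for (j in seq_len(ncol(idx))) consider(zeros[idx[, j]])
    }
  }
  best
}

#' Extract subnetworks for all three indicator variants
#'
#' Runs the greedy solver once per indicator variant (all / up / down) and
#' summarises node and edge counts per variant.
#'
#' @param g igraph interactome.
#' @param indicators An `indicator_set` from [binarize()].
#' @param K Exception budget (default 5).
#' @return List with the three `subnetwork_solution`s plus a `summary`
#'   data frame (variant, n_nodes, n_edges, de_count, n_exceptions).
#' @export
extract_all_variants <- function(g, indicators, K = 5) {
  stopifnot(inherits(indicators, "indicator_set"))
  sols <- lapply(c(all = "all", up = "up", down = "down"), function(v) {
    withCallingHandlers(
      greedy_max_subnetwork(g, indicators[[v]], K = K, variant = v),
      warning = function(w) {
        if (grepl("no indicator-1 node", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  summary <- do.call(rbind, lapply(sols, function(s) {
    data.frame(variant = s$variant, n_nodes = length(s$nodes),
               n_edges = nrow(s$edges), de_count = s$de_count,
               n_exceptions = length(s$exceptions), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  c(sols, list(summary = summary))
}

#' Write a subnetwork solution to TSV files
#'
#' @param sol A `subnetwork_solution`.
#' @param ind Named indicator vector used when the solution was extracted.
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`.
#' @export
write_subnetwork <- function(sol, ind, prefix) {
  utils::write.table(sol$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodes <- data.frame(symbol = sol$nodes,
                      indicator = as.integer(ind[sol$nodes]),
                      is_exception = as.integer(sol$nodes %in% sol$exceptions),
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
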