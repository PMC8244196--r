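#' Read a protein-protein interaction network
#'
#' Supported formats: a 2-column edge list (`edge_tsv`, tab- or
#' whitespace-separated, `#` comments allowed), Cytoscape SIF (`sif`,
#' `node relation target1 target2 ...`), and BioGRID TAB3 (`biogrid_tab3`,
#' tab-delimited with header; the two "Official Symbol Interactor" columns
#' are used and, when an "Experimental System Type" column is present,
#' rows are restricted to physical interactions unless `physical_only =
#' FALSE`). Gene symbols are uppercased and whitespace-stripped;
#' self-loops and duplicate edges are removed. The whole network is kept,
#' including disconnected parts.
#'
#' @param path Input file.
#' @param format One of `"edge_tsv"`, `"sif"`, `"biogrid_tab3"`.
#' @param physical_only Keep only physical interactions for BioGRID input.
#' @return An undirected simple `igraph` graph with uppercase symbol names.
#' @export
read_network <- function(path, format = c("edge_tsv", "sif", "biogrid_tab3"),
                         physical_only = TRUE) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty network file: ", path)

  pairs <- switch(format,
    edge_tsv = {
      keep <- !grepl("^\\s*(#|$)", lines)
      out <- vector("list", sum(keep))
      k <- 0
      for (i in which(keep)) {
        f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
        if (length(f) != 2) stop("malformed edge list line ", i, ": '", lines[i], "'")
        k <- k + 1; out[[k]] <- f
      }
      out
    },
    sif = {
      keep <- !grepl("^\\s*(#|$)", lines)
      out <- list()
      for (i in which(keep)) {
        f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
        if (length(f) == 1) next  # isolated node lines carry no edges
        if (length(f) == 2) stop("malformed SIF line ", i, ": '", lines[i], "'")
        for (tgt in f[-(1:2)]) out[[length(out) + 1]] <- c(f[1], tgt)
      }
      out
    },
    biogrid_tab3 = {
      df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
      ca <- grep("^Official Symbol Interactor A$", names(df))
      cb <- grep("^Official Symbol Interactor B$", names(df))
      if (!length(ca) || !length(cb)) {
        stop("BioGRID TAB3 file lacks 'Official Symbol Interactor A/B' columns")
      }
      ct <- grep("^Experimental System Type$", names(df))
      if (physical_only && length(ct)) {
        df <- df[tolower(df[[ct[1]]]) == "physical", , drop = FALSE]
      }
      mapply(c, df[[ca[1]]], df[[cb[1]]], SIMPLIFY = FALSE, USE.NAMES = FALSE)
    })

  if (!length(pairs)) stop("no edges parsed from ", path)
  a <- toupper(trimws(vapply(pairs, `[`, "", 1)))
  b <- toupper(trimws(vapply(pairs, `[`, "", 2)))
  ok <- a != b & nzchar(a) & nzchar(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("network empty after removing self-loops: ", path)
  lo <- pmin(a, b); hi <- pmax(a, b)
  dedup <- !duplicated(paste0(lo, "\t", hi))
  g <- igraph::graph_from_edgelist(cbind(lo[dedup], hi[dedup]), directed = FALSE)
  # sort vertices so all downstream traversals are order-independent
  igraph::permute(g, rank(igraph::V(g)$name, ties.method = "first"))
}

#' Write a network as a 2-column edge list
#'
#' Edges are written in deterministic sorted order.
#'
#' @param g An igraph graph.
#' @param path Output path.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  o <- order(lo, hi)
  utils::write.table(data.frame(a = lo[o], b = hi[o]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach a differential-expression indicator to network nodes
#'
#' Nodes absent from the indicator default to 0: an unmeasured interactome
#' gene is treated as not differentially expressed. Symbols are matched
#' after uppercasing.
#'
#' @param g An igraph interactome.
#' @param ind Named 0/1 vector (one of the [binarize()] variants).
#' @return List with `indicator` (named 0/1 vector over all nodes of `g`)
#'   and `n_de` (number of indicator-1 nodes present in the graph).
#' @export
attach_indicator <- function(g, ind) {
  nodes <- igraph::V(g)$name
  out <- stats::setNames(integer(length(nodes)), nodes)
  if (length(ind)) {
    names(ind) <- toupper(trimws(names(ind)))
    hit <- intersect(nodes, names(ind)[ind == 1])
    out[hit] <- 1L
  }
  n_de <- sum(out)
  if (n_de == 0) warning("no indicator-1 genes present in the network; ",
                         "subnetwork extraction will be empty")
  list(indicator = out, n_de = n_de)
}
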