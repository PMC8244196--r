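#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: tab-separated lines `term<TAB>description<TAB>gene...`.
#' Term keys are namespaced `db::term`; genes are uppercased and
#' deduplicated per term.
#'
#' @param path GMT file.
#' @param db Collection name used for namespacing (default: file name
#'   without extension).
#' @return Object of class `gene_set_collection`: list with `sets` (named
#'   list of uppercase gene vectors) and `db` (named vector term -> db).
#' @export
read_gmt <- function(path, db = NULL) {
  stopifnot(file.exists(path))
  if (is.null(db)) db <- sub("\\.gmt$", "", basename(path), ignore.case = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, " has no genes (term '", f[1], "')")
    key <- paste0(db, "::", trimws(f[1]))
    if (key %in% names(sets)) stop("duplicate term at GMT line ", i, ": ", key)
    genes <- unique(toupper(trimws(f[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " has no genes (term '", f[1], "')")
    sets[[key]] <- sort(genes)
  }
  gene_set_collection(sets)
}

#' Construct a gene-set collection from a named list
#'
#' @param sets Named list of gene symbol vectors; names should be
#'   namespaced `db::term`.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  sets <- lapply(sets, function(s) sort(unique(toupper(trimws(s)))))
  if (any(lengths(sets) == 0)) stop("empty gene set in collection")
  db <- sub("::.*$", "", names(sets))
  db[!grepl("::", names(sets))] <- "custom"
  structure(list(sets = sets, db = stats::setNames(db, names(sets))),
            class = "gene_set_collection")
}

#' Merge gene-set collections
#' @param ... `gene_set_collection` objects.
#' @return A single merged `gene_set_collection`.
#' @export
merge_collections <- function(...) {
  colls <- list(...)
  sets <- do.call(c, lapply(colls, `[[`, "sets"))
  if (anyDuplicated(names(sets))) {
    stop("duplicate term keys across collections: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  gene_set_collection(sets)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term for over-representation of the query genes within a
#' gene universe using the upper-tail hypergeometric distribution
#' (one-sided Fisher test). Query genes outside the universe are dropped
#' (count reported via message); term sets are likewise intersected with
#' the universe. FDR is Benjamini-Hochberg, by default computed within
#' each source database separately.
#'
#' @param query Character vector of gene symbols.
#' @param coll A `gene_set_collection`.
#' @param universe Gene universe; default = all genes annotated anywhere
#'   in the collection.
#' @param bh_per_db Adjust p-values within each database separately
#'   (default TRUE); FALSE pools all terms.
#' @return Data frame with one row per term: `term`, `db`, `k`, `K_term`,
#'   `n_query`, `N`, `p_value`, `fdr`, `overlap_genes` (comma-joined),
#'   ordered by p-value then term.
#' @export
ora <- function(query, coll, universe = NULL, bh_per_db = TRUE) {
  stopifnot(inherits(coll, "gene_set_collection"))
  query <- unique(toupper(trimws(query)))
  if (is.null(universe)) {
    universe <- unique(unlist(coll$sets, use.names = FALSE))
  } else {
    universe <- unique(toupper(trimws(universe)))
  }
  if (!length(universe)) stop("empty universe")
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(length(dropped), " query gene(s) outside the universe dropped")
  }
  query <- intersect(query, universe)
  if (!length(query)) stop("query empty after universe intersection")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(coll$sets), function(term) {
    set <- intersect(coll$sets[[term]], universe)
    overlap <- sort(intersect(query, set))
    k <- length(overlap)
    K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, db = unname(coll$db[term]), k = k, K_term = K,
               n_query = n, N = N, p_value = p,
               overlap_genes = paste(overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- if (bh_per_db) {
    stats::ave(out$p_value, out$db,
               FUN = function(p) stats::p.adjust(p, method = "BH"))
  } else {
    stats::p.adjust(out$p_value, method = "BH")
  }
  out <- out[order(out$p_value, out$term),
             c("term", "db", "k", "K_term", "n_query", "N", "p_value", "fdr",
               "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Filter enrichment results by FDR, keyword and overlap size
#'
#' Keeps rows with `fdr < fdr_max`, at least one case-insensitive keyword
#' substring match in the term name (internal whitespace collapsed before
#' matching), and at least `min_genes` overlap genes.
#'
#' @param rows Data frame from [ora()].
#' @param fdr_max FDR cutoff (default 0.05).
#' @param keywords Character vector of keywords (default `signal`,
#'   `apoptosis`, `cell cycle`).
#' @param min_genes Minimum overlap size (default 3).
#' @return The filtered data frame (possibly empty, with a warning).
#' @export
filter_pathways <- function(rows, fdr_max = 0.05,
                            keywords = c("signal", "apoptosis", "cell cycle"),
                            min_genes = 3) {
  squash <- function(x) gsub("\\s+", " ", tolower(x))
  disp <- squash(sub("^[^:]*::", "", rows$term))
  kw <- squash(keywords)
  hit_kw <- Reduce(`|`, lapply(kw, function(k) grepl(k, disp, fixed = TRUE)),
                   accumulate = FALSE)
  if (is.null(hit_kw)) hit_kw <- rep(FALSE, nrow(rows))
  keep <- rows$fdr < fdr_max & hit_kw & rows$k >= min_genes
  out <- rows[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no pathways survive the filters")
  rownames(out) <- NULL
  out
}

#' Split comma-joined overlap genes back into sets
#'
#' @param rows Enrichment data frame.
#' @return Named list (term -> character vector of overlap genes).
#' @export
overlap_sets <- function(rows) {
  stats::setNames(lapply(strsplit(rows$overlap_genes, ",", fixed = TRUE),
                         function(x) x[nzchar(x)]),
                  rows$term)
}
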