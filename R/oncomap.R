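# Mapping of enriched pathway terms onto the canonical oncogenic
# signalling pathways (the ten TCGA Pan-Cancer pathways plus immune
# signalling) and onto three carcinogenesis process categories. Matching
# is substring-based against a curated, user-editable synonym dictionary;
# the tool reports the supporting overlap genes so a user can arbitrate
# multi-category calls rather than inventing a functional call itself.

PROCESS_CATEGORIES <- c("proliferation_apoptosis", "metastasis_invasion",
                        "angiogenesis")

#' Read a canonical-pathway synonym dictionary
#'
#' TSV columns: `canonical_id`, `pattern` (case-insensitive substring
#' matched against term names), `categories` (semicolon-separated process
#' categories from `proliferation_apoptosis`, `metastasis_invasion`,
#' `angiogenesis`), optional `note`. The default shipped dictionary covers
#' the ten canonical oncogenic signalling pathways (cell cycle, Hippo,
#' Myc, Notch, NRF2, PI3K/Akt, RTK-RAS-MAPK, TGF-beta, p53,
#' Wnt/beta-catenin) plus an immune-signalling group whose default
#' category is proliferation/apoptosis with a tumour-microenvironment
#' note.
#'
#' @param path Dictionary TSV; default = the shipped dictionary.
#' @return Data frame of class `canonical_dictionary`.
#' @export
read_canonical_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "canonical_pathways.tsv", package = "moanet")
  }
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "#")
  stopifnot(all(c("canonical_id", "pattern", "categories") %in% names(d)))
  if (any(!nzchar(trimws(d$pattern)))) stop("empty pattern in dictionary")
  if (!all(table(d$canonical_id) >= 1)) stop("canonical id without pattern")
  cats <- unique(unlist(strsplit(d$categories, ";", fixed = TRUE)))
  bad <- setdiff(trimws(cats), PROCESS_CATEGORIES)
  if (length(bad)) stop("unknown process categories: ", paste(bad, collapse = ", "))
  class(d) <- c("canonical_dictionary", class(d))
  d
}

squash_term <- function(x) gsub("\\s+", " ", tolower(trimws(x)))

#' Match a pathway term against the canonical dictionary
#'
#' Case-insensitive substring matching of every synonym pattern against
#' the term display name (namespace prefix removed, internal whitespace
#' collapsed). Multiple canonical matches are allowed; an empty result
#' flags the term for manual review.
#'
#' @param term Term name (possibly `db::term` namespaced).
#' @param dict A `canonical_dictionary`.
#' @return Character vector of matched canonical ids (possibly empty).
#' @export
match_canonical <- function(term, dict) {
  disp <- squash_term(sub("^[^:]*::", "", term))
  hit <- vapply(squash_term(dict$pattern),
                function(p) grepl(p, disp, fixed = TRUE), logical(1))
  unique(dict$canonical_id[hit])
}

#' Assign regulation direction to a pathway term
#'
#' Direction comes from the directional subnetwork enrichments: `up` if
#' the term is significant only in the up-regulated subnetwork's
#' enrichment, `down` if only in the down-regulated one, `both` if in
#' both, `unresolved` if in neither (significant only in the combined
#' subnetwork).
#'
#' @param term Term key.
#' @param up_rows,down_rows Enrichment data frames from the up/down
#'   subnetwork variants.
#' @param fdr_max Significance cutoff (default 0.05).
#' @return One of `"up"`, `"down"`, `"both"`, `"unresolved"`.
#' @export
assign_direction <- function(term, up_rows, down_rows, fdr_max = 0.05) {
  sig <- function(rows) {
    !is.null(rows) && nrow(rows) > 0 && term %in% rows$term &&
      rows$fdr[match(term, rows$term)] < fdr_max
  }
  u <- sig(up_rows); d <- sig(down_rows)
  if (u && d) "both" else if (u) "up" else if (d) "down" else "unresolved"
}

#' Map retained pathway terms onto canonical pathways and processes
#'
#' For every retained term: canonical matches from the dictionary, the
#' process category(ies) of each matched synonym row (a canonical pathway
#' allowed several categories yields one output row per category, with the
#' term's overlap genes attached as supporting evidence), and the
#' up/down/both/unresolved direction from the directional enrichments.
#' Unmatched terms are kept with `canonical_id = NA` and
#' `matched = 0` so nothing is dropped silently.
#'
#' @param rows Retained (representative) enrichment rows.
#' @param up_rows,down_rows Directional enrichment tables (may be NULL).
#' @param dict A `canonical_dictionary` (default: shipped).
#' @param fdr_max Directional significance cutoff (default 0.05).
#' @return Data frame: `term`, `canonical_id`, `category`, `direction`,
#'   `genes`, `matched`, `note`.
#' @export
map_oncogenic <- function(rows, up_rows = NULL, down_rows = NULL,
                          dict = read_canonical_dictionary(),
                          fdr_max = 0.05) {
  out <- list()
  for (i in seq_len(nrow(rows))) {
    term <- rows$term[i]
    genes <- rows$overlap_genes[i]
    dir <- assign_direction(term, up_rows, down_rows, fdr_max)
    disp <- squash_term(sub("^[^:]*::", "", term))
    hit <- vapply(squash_term(dict$pattern),
                  function(p) grepl(p, disp, fixed = TRUE), logical(1))
    if (!any(hit)) {
      out[[length(out) + 1]] <- data.frame(
        term = term, canonical_id = NA_character_, category = NA_character_,
        direction = dir, genes = genes, matched = 0L, note = "unmatched; review",
        stringsAsFactors = FALSE)
      next
    }
    sub <- dict[hit, , drop = FALSE]
    for (cid in unique(sub$canonical_id)) {
      cats <- unique(trimws(unlist(strsplit(
        sub$categories[sub$canonical_id == cid], ";", fixed = TRUE))))
      note <- if ("note" %in% names(sub)) {
        nts <- unique(sub$note[sub$canonical_id == cid])
        paste(nts[nzchar(nts)], collapse = "; ")
      } else ""
      for (cat in sort(cats)) {
        out[[length(out) + 1]] <- data.frame(
          term = term, canonical_id = cid, category = cat, direction = dir,
          genes = genes, matched = 1L, note = note, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(term = character(0), canonical_id = character(0),
               category = character(0), direction = character(0),
               genes = character(0), matched = integer(0), note = character(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$term, res$canonical_id, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}
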