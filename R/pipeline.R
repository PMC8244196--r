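#' Assemble a pipeline configuration
#'
#' Defaults carry the standard analysis parameters: linear fold-change
#' cutoff 2, FDR cutoff 5e-3 (alternative preset 1e-2 for noisier
#' datasets), exception budget K = 5, ORA FDR < 0.05, keyword filter
#' (signal / apoptosis / cell cycle), minimum 3 overlap genes, Jaccard
#' redundancy cutoff 0.60 (strict) and crosstalk cutoff 0.25 (inclusive),
#' top 5 hub genes. Values from a YAML file override the defaults, and
#' direct arguments override both (flags > file > defaults).
#'
#' @param config_file Optional YAML file with config entries.
#' @param ... Direct overrides (e.g. `fdr_cutoff = 1e-2`, `paths = list(...)`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- list(
    fc_cutoff = 2, fdr_cutoff = 5e-3, K = 5, ora_fdr_max = 0.05,
    keywords = c("signal", "apoptosis", "cell cycle"),
    min_overlap_genes = 3, redundancy_cutoff = 0.60, crosstalk_cutoff = 0.25,
    top_n = 5, universe_mode = "collection", scale = NULL, seed = 1,
    paths = list(expression = NULL, samples = NULL, network = NULL,
                 network_format = "edge_tsv", gmt = NULL, gmt_db = NULL,
                 probe_map = NULL, dictionary = NULL))
  if (!is.null(config_file)) {
    stopifnot(file.exists(config_file))
    file_cfg <- yaml::read_yaml(config_file)
    for (k in names(file_cfg)) {
      if (k == "paths") {
        for (p in names(file_cfg$paths)) cfg$paths[[p]] <- file_cfg$paths[[p]]
      } else cfg[[k]] <- file_cfg[[k]]
    }
  }
  over <- list(...)
  for (k in names(over)) {
    if (k == "paths") {
      for (p in names(over$paths)) cfg$paths[[p]] <- over$paths[[p]]
    } else cfg[[k]] <- over[[k]]
  }
  cfg$keywords <- as.character(unlist(cfg$keywords))
  cfg$paths <- lapply(cfg$paths, function(x) if (is.null(x)) x else unlist(x))
  stopifnot(cfg$fc_cutoff > 1, cfg$fdr_cutoff > 0, cfg$fdr_cutoff < 1,
            cfg$K >= 0, cfg$ora_fdr_max > 0, cfg$ora_fdr_max < 1,
            cfg$min_overlap_genes >= 1,
            cfg$redundancy_cutoff >= 0, cfg$redundancy_cutoff <= 1,
            cfg$crosstalk_cutoff >= 0, cfg$crosstalk_cutoff <= 1,
            cfg$top_n >= 1,
            cfg$universe_mode %in% c("collection", "network", "measured"))
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full mechanism-of-action pipeline
#'
#' Stages, in order: expression input (optional probe collapse, low-count
#' filter, log2 normalization), PCA screen (advisory), moderated
#' differential expression, binarization into all/up/down indicators,
#' K-exception subnetwork extraction per variant, centrality ranking,
#' over-representation analysis per variant, keyword/FDR/size filtering,
#' redundancy collapse, crosstalk network construction and clustering,
#' and canonical oncogenic pathway / process assignment. Every stage's
#' outputs and parameters are recorded in `manifest.json`; the run is
#' deterministic given config + seed, and empty intermediate results
#' yield warnings plus empty-but-valid downstream outputs.
#'
#' @param config A `pipeline_config` with valid input paths.
#' @param out_dir Output run directory (created).
#' @return Invisibly, a list with the principal in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- file(log_path, open = "wt")
  on.exit(close(logf), add = TRUE)
  info <- function(stage, msg) {
    line <- sprintf("INFO [%s] %s", stage, msg)
    writeLines(line, logf)
    message(line)
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  manifest <- list(tool = "moanet",
                   version = as.character(utils::packageVersion("moanet")),
                   config = unclass(config), stages = list())
  note_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  p <- config$paths
  set.seed(config$seed)

  # --- expression ---
  expr <- stage_wrap("expression", {
    sheet <- read_sample_sheet(p$samples)
    m <- read_expression(p$expression, sheet, scale = config$scale)
    if (!is.null(p$probe_map)) {
      pm <- utils::read.delim(p$probe_map, stringsAsFactors = FALSE)
      m <- collapse_probes(m, pm)
    }
    if (m$scale == "counts") m <- filter_low_counts(m)
    if (m$scale != "log2") m <- log2_normalize(m)
    m
  })
  info("expression", sprintf("%d genes x %d samples", nrow(expr$values),
                             ncol(expr$values)))
  note_stage("expression", n_genes = nrow(expr$values),
             n_samples = ncol(expr$values), scale = expr$scale)

  qc <- stage_wrap("pca_qc", pca_qc(expr))
  info("pca_qc", sprintf("separated=%s", qc$separated))
  if (!qc$separated) warning("PCA screen: control/treatment samples do not separate (advisory)")
  write_tsv(format_num(qc$coords, c("PC1", "PC2")), file.path(out_dir, "pca_qc.tsv"))
  note_stage("pca_qc", separated = qc$separated)

  # --- differential expression + binarization ---
  de <- stage_wrap("diffexp", differential_expression(expr))
  ind <- binarize(de, config$fc_cutoff, config$fdr_cutoff)
  de_out <- de
  de_out$indicator_all <- unname(ind$all[de$gene])
  de_out$indicator_up <- unname(ind$up[de$gene])
  de_out$indicator_down <- unname(ind$down[de$gene])
  de_out <- de_out[order(de_out$gene), , drop = FALSE]
  write_tsv(format_num(de_out, c("log2fc", "t_stat", "p_value", "fdr")),
            file.path(out_dir, "de_table.tsv"))
  info("diffexp", sprintf("%d DE genes (all), %d up, %d down",
                          sum(ind$all), sum(ind$up), sum(ind$down)))
  note_stage("diffexp", n_de_all = sum(ind$all), n_de_up = sum(ind$up),
             n_de_down = sum(ind$down), d0 = attr(de, "d0"))

  # --- interactome + subnetworks ---
  g <- stage_wrap("interactome", read_network(p$network, config$paths$network_format))
  info("interactome", sprintf("%d nodes, %d edges", igraph::vcount(g),
                              igraph::ecount(g)))
  sols <- stage_wrap("subnetwork", extract_all_variants(g, ind, K = config$K))
  for (v in c("all", "up", "down")) {
    write_subnetwork(sols[[v]], normalize_indicator(g, ind[[v]]),
                     file.path(out_dir, paste0("subnetwork_", v)))
  }
  write_tsv(sols$summary, file.path(out_dir, "subnetwork_summary.tsv"))
  info("subnetwork", paste(utils::capture.output(print(sols$summary)), collapse = " | "))
  note_stage("subnetwork", summary = sols$summary)

  # --- centrality ---
  cent <- if (length(sols$all$nodes)) {
    tg <- top_genes(compute_centrality(sols$all), n = config$top_n)
    write_tsv(format_num(tg, c("betweenness", "rank_betweenness", "rank_degree",
                               "composite_score")),
              file.path(out_dir, "centrality.tsv"))
    tg
  } else {
    warning("empty subnetwork; centrality skipped")
    empty <- data.frame(gene = character(0), degree = integer(0),
                        betweenness = numeric(0))
    write_tsv(empty, file.path(out_dir, "centrality.tsv"))
    empty
  }
  note_stage("centrality",
             top_genes = if (nrow(cent)) cent$gene[cent$top_n_flag == 1] else character(0))

  # --- enrichment per variant ---
  coll <- stage_wrap("enrichment", {
    gmts <- p$gmt
    dbs <- if (!is.null(p$gmt_db)) p$gmt_db else rep(list(NULL), length(gmts))
    colls <- mapply(function(path, db) read_gmt(path, db = db), gmts, dbs,
                    SIMPLIFY = FALSE)
    if (length(colls) > 1) do.call(merge_collections, colls) else colls[[1]]
  })
  universe <- switch(config$universe_mode,
                     collection = NULL,
                     network = igraph::V(g)$name,
                     measured = rownames(expr$values))
  enr <- list()
  for (v in c("all", "up", "down")) {
    rows <- if (length(sols[[v]]$nodes)) {
      suppressMessages(ora(sols[[v]]$nodes, coll, universe = universe))
    } else {
      data.frame(term = character(0), db = character(0), k = integer(0),
                 K_term = integer(0), n_query = integer(0), N = integer(0),
                 p_value = numeric(0), fdr = numeric(0),
                 overlap_genes = character(0), stringsAsFactors = FALSE)
    }
    enr[[v]] <- rows
    write_tsv(format_num(rows, c("p_value", "fdr")),
              file.path(out_dir, paste0("enrichment_", v, ".tsv")))
  }
  retained <- withCallingHandlers(
    filter_pathways(enr$all, fdr_max = config$ora_fdr_max,
                    keywords = config$keywords,
                    min_genes = config$min_overlap_genes),
    warning = function(w) invokeRestart("muffleWarning"))
  info("enrichment", sprintf("%d terms tested, %d retained after filters",
                             nrow(enr$all), nrow(retained)))
  note_stage("enrichment", n_terms = nrow(enr$all), n_retained = nrow(retained))

  # --- pathway network ---
  coll_res <- collapse_redundant(retained, config$redundancy_cutoff)
  pg <- build_crosstalk_network(coll_res$representatives,
                                config$crosstalk_cutoff,
                                config$redundancy_cutoff)
  pg <- cluster_pathways(pg)
  write_pathway_network(pg, coll_res$redundancy_map,
                        file.path(out_dir, "pathway_network"))
  info("pathway_network", sprintf("%d representatives, %d edges, %d clusters",
                                  nrow(pg$nodes), nrow(pg$edges),
                                  length(unique(pg$clusters))))
  note_stage("pathway_network", n_representatives = nrow(pg$nodes),
             n_edges = nrow(pg$edges),
             n_clusters = length(unique(pg$clusters)))

  # --- oncogenic mapping ---
  dict <- if (!is.null(p$dictionary)) read_canonical_dictionary(p$dictionary)
          else read_canonical_dictionary()
  assign <- map_oncogenic(pg$nodes, enr$up, enr$down, dict = dict,
                          fdr_max = config$ora_fdr_max)
  write_tsv(assign, file.path(out_dir, "process_assignments.tsv"))
  info("oncomap", sprintf("%d assignment rows (%d terms matched)",
                          nrow(assign), length(unique(assign$term[assign$matched == 1]))))
  note_stage("oncomap", n_rows = nrow(assign),
             n_matched_terms = length(unique(assign$term[assign$matched == 1])))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(list(expr = expr, qc = qc, de = de, indicators = ind, graph = g,
                 subnetworks = sols, centrality = cent, enrichment = enr,
                 retained = retained, pathway_graph = pg,
                 redundancy_map = coll_res$redundancy_map,
                 assignments = assign, manifest = manifest))
}

#' Re-run a pipeline from its manifest
#'
#' The manifest records the full configuration verbatim, so a run can be
#' reproduced bit-for-bit into a fresh directory.
#'
#' @param manifest_path Path to a `manifest.json` from [run_pipeline()].
#' @param out_dir New output directory.
#' @return As [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  paths <- as.list(cfg$paths)
  paths <- paths[!vapply(paths, function(x) is.null(x) || all(is.na(x)), logical(1))]
  cfg$paths <- NULL
  cfg <- cfg[!vapply(cfg, function(x) is.null(x) || all(is.na(x)), logical(1))]
  do.call(pipeline_config, c(cfg, list(paths = paths))) |>
    run_pipeline(out_dir)
}
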