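# Seeded synthetic inputs with known ground truth: a scale-free
# interactome, a planted connected differentially-expressed module, a
# two-group expression matrix with log2 mean-shift signal plus Gaussian
# noise, and a GMT collection whose pairwise Jaccard overlaps are realized
# exactly by construction. Every generator is a pure function of its seed.

#' Simulate a scale-free interactome
#'
#' Barabasi-Albert preferential attachment: each new node attaches to
#' `attach` existing nodes, yielding a connected scale-free graph with
#' labels `G0001`, `G0002`, ...
#'
#' @param n Number of nodes (`n > attach`).
#' @param attach Edges added per incoming node (>= 1).
#' @param seed Integer seed.
#' @return An igraph interactome.
#' @export
simulate_interactome <- function(n, attach = 2, seed = 1) {
  stopifnot(attach >= 1)
  if (n <= attach) stop("need n > attach (got n=", n, ", attach=", attach, ")")
  labels <- sprintf("G%04d", seq_len(n))
  withr_seed(seed, {
    g <- igraph::sample_pa(n, m = attach, directed = FALSE)
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- labels
  g
}

# localized seeded evaluation that restores the RNG state afterwards
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Plant a connected module with exception nodes
#'
#' Grows a random connected subgraph of the requested size by seeded BFS
#' with random frontier order, then marks `n_exceptions` members as
#' exceptions (indicator 0). Exceptions are placed only on nodes whose
#' removal keeps the remaining module members connected, so the module
#' stays recoverable with exception budget `K = n_exceptions`.
#'
#' @param g igraph interactome.
#' @param size Module size (<= number of nodes).
#' @param n_exceptions Number of exception members (< size).
#' @param seed Integer seed.
#' @return List of class `fixture_truth` (partial): `module`,
#'   `exceptions`, `de_genes`, `seed`.
#' @export
plant_module <- function(g, size, n_exceptions = 0, seed = 1) {
  n <- igraph::vcount(g)
  if (size > n) stop("module size ", size, " exceeds graph size ", n)
  stopifnot(n_exceptions < size, n_exceptions >= 0)
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), function(v) sort(v$name))
  names(adj) <- nodes
  module <- withr_seed(seed, {
    start <- sample(nodes, 1)
    mem <- start
    frontier <- setdiff(adj[[start]], mem)
    while (length(mem) < size) {
      if (!length(frontier)) stop("graph too small/fragmented to grow module")
      nxt <- sample(frontier, 1)
      mem <- c(mem, nxt)
      frontier <- setdiff(unique(c(frontier, adj[[nxt]])), mem)
    }
    sort(mem)
  })
  exceptions <- character(0)
  if (n_exceptions > 0) {
    sg <- igraph::induced_subgraph(g, module)
    # candidates whose removal keeps the DE part of the module connected
    exceptions <- withr_seed(seed + 1, {
      chosen <- character(0)
      pool <- sample(module)
      for (cand in pool) {
        if (length(chosen) == n_exceptions) break
        rest <- setdiff(module, c(chosen, cand))
        if (length(rest) == 0) next
        if (igraph::is_connected(igraph::induced_subgraph(sg, rest))) {
          chosen <- c(chosen, cand)
        }
      }
      if (length(chosen) < n_exceptions) {
        stop("could not place ", n_exceptions, " removable exception nodes")
      }
      sort(chosen)
    })
  }
  structure(list(module = module, exceptions = exceptions,
                 de_genes = setdiff(module, exceptions), seed = seed),
            class = "fixture_truth")
}

#' Simulate a two-group log2 expression matrix over the interactome genes
#'
#' Every gene gets baseline `N(mu_g, sigma^2)` noise in both groups
#' (baselines drawn uniformly in `[4, 10]` log2 units); planted
#' differentially expressed genes receive a treatment-group mean shift of
#' `+delta` (or `-delta` for a `1 - prop_up` fraction; signs are recorded
#' in the returned truth). Exception genes get shift 0.
#'
#' @param g igraph interactome.
#' @param truth A `fixture_truth` from [plant_module()].
#' @param delta Log2 mean shift of planted genes (default 2).
#' @param sigma Gaussian noise SD in log2 units (default 0.5).
#' @param n_ctrl,n_trt Samples per group (default 5 and 5).
#' @param prop_up Fraction of planted DE genes shifted upward (default 1).
#' @param seed Integer seed.
#' @return List with `expr` (a log2-scale `expr_matrix`) and `truth`
#'   (input truth with a named `sign` vector over DE genes added).
#' @export
simulate_expression <- function(g, truth, delta = 2, sigma = 0.5,
                                n_ctrl = 5, n_trt = 5, prop_up = 1,
                                seed = 1) {
  stopifnot(delta != 0, sigma > 0, n_ctrl >= 2, n_trt >= 2,
            prop_up >= 0, prop_up <= 1)
  genes <- sort(igraph::V(g)$name)
  samples <- c(sprintf("ctrl%02d", seq_len(n_ctrl)),
               sprintf("trt%02d", seq_len(n_trt)))
  sheet <- data.frame(sample_id = samples,
                      group = rep(c("control", "treatment"), c(n_ctrl, n_trt)),
                      stringsAsFactors = FALSE)
  de <- truth$de_genes
  vals <- withr_seed(seed, {
    mu <- stats::runif(length(genes), 4, 10)
    m <- matrix(stats::rnorm(length(genes) * length(samples), mean = mu,
                             sd = sigma),
                nrow = length(genes), ncol = length(samples))
    n_up <- round(prop_up * length(de))
    sign_vec <- stats::setNames(rep(-1, length(de)), de)
    if (n_up > 0) sign_vec[sample(de, n_up)] <- 1
    shift <- stats::setNames(numeric(length(genes)), genes)
    shift[de] <- delta * sign_vec[de]
    trt_cols <- n_ctrl + seq_len(n_trt)
    m[, trt_cols] <- m[, trt_cols] + shift
    list(m = m, sign = sign_vec)
  })
  m <- vals$m
  rownames(m) <- genes
  colnames(m) <- samples
  truth$sign <- vals$sign
  list(expr = expr_matrix(m, "log2", sheet), truth = truth)
}

# integer intersection size c realizing J = c/(a + b - c) for set sizes a, b
jaccard_overlap_size <- function(a, b, j) {
  if (j == 0) return(0L)
  c_exact <- j * (a + b) / (1 + j)
  if (abs(c_exact - round(c_exact)) < 1e-9 && round(c_exact) >= 1 &&
      round(c_exact) <= min(a, b)) {
    return(as.integer(round(c_exact)))
  }
  NA_integer_
}

suggest_feasible_sizes <- function(a, j, b_range = 3:30) {
  ok <- vapply(b_range, function(b) !is.na(jaccard_overlap_size(a, b, j)),
               logical(1))
  b_range[ok]
}

#' Simulate a GMT collection with controlled pairwise overlaps
#'
#' Builds one "true" pathway term containing all planted module genes
#' plus, for each overlap request, a decoy term whose Jaccard index with
#' the true term is realized exactly: a decoy of size `b` sharing `c`
#' genes with the true term (size `a`) has `J = c/(a + b - c)`, so `c`
#' must be the integer `J (a + b) / (1 + J)` — infeasible requests raise
#' an error listing feasible sizes. Shared genes are drawn from the
#' planted module (preferring DE genes) so that the overlap survives into
#' the enriched gene sets; decoy-only genes are synthetic `DEC####`
#' symbols absent from the interactome. Random filler terms over
#' interactome genes and a known-negative term disjoint from the module
#' are added, and every term name contains "signaling" so the collection
#' survives the keyword filter.
#'
#' @param truth A `fixture_truth` (needs `module`, `de_genes`).
#' @param g igraph interactome (source of filler genes).
#' @param n_filler Number of random filler terms (default 5).
#' @param overlap_spec Data frame with columns `name`, `size`, `j`: one
#'   decoy per row with target Jaccard `j` to the true term.
#' @param true_name Display name of the true term; the default carries an
#'   NRF2 synonym so the term maps onto a canonical oncogenic pathway.
#' @param db Collection namespace (default "synthetic").
#' @param seed Integer seed.
#' @return List with `collection` (a `gene_set_collection`) and `truth`
#'   (input truth plus `true_term`, `negative_term` and `realized_j`).
#' @export
simulate_gmt <- function(truth, g, n_filler = 5,
                         overlap_spec = NULL,
                         true_name = "NRF2 oxidative stress response signaling",
                         db = "synthetic", seed = 1) {
  module <- truth$module
  a <- length(module)
  sets <- list()
  true_key <- paste0(db, "::", true_name)
  sets[[true_key]] <- module
  realized <- numeric(0)
  if (!is.null(overlap_spec)) {
    stopifnot(all(c("name", "size", "j") %in% names(overlap_spec)))
    dec_counter <- 0
    for (i in seq_len(nrow(overlap_spec))) {
      b <- overlap_spec$size[i]; j <- overlap_spec$j[i]
      stopifnot(j >= 0, j <= 1)
      cc <- jaccard_overlap_size(a, b, j)
      if (is.na(cc)) {
        feas <- suggest_feasible_sizes(a, j)
        stop(sprintf(
          "target J=%g unrealizable with sizes (%d, %d): c = J(a+b)/(1+J) = %.4g is not a valid integer; feasible decoy sizes for this J: %s",
          j, a, b, j * (a + b) / (1 + j),
          if (length(feas)) paste(feas, collapse = ", ") else "none in 3..30"))
      }
      shared <- withr_seed(seed + i, {
        pref <- c(sort(truth$de_genes), sort(setdiff(module, truth$de_genes)))
        pref[seq_len(cc)]
      })
      extra <- character(0)
      if (b > cc) {
        extra <- sprintf("DEC%04d", dec_counter + seq_len(b - cc))
        dec_counter <- dec_counter + (b - cc)
      }
      key <- paste0(db, "::", overlap_spec$name[i])
      sets[[key]] <- c(shared, extra)
      realized[key] <- jaccard(sets[[true_key]], sets[[key]])
      stopifnot(abs(realized[key] - j) < 1e-9)
    }
  }
  # filler terms from off-module interactome genes; negative term disjoint
  # from the module
  offmod <- sort(setdiff(igraph::V(g)$name, module))
  filler <- withr_seed(seed + 1000, {
    out <- list()
    for (i in seq_len(n_filler)) {
      sz <- sample(8:15, 1)
      out[[sprintf("%s::background signaling process %02d", db, i)]] <-
        sample(offmod, min(sz, length(offmod)))
    }
    out
  })
  sets <- c(sets, filler)
  neg_key <- paste0(db, "::negative control signaling")
  sets[[neg_key]] <- withr_seed(seed + 2000, {
    sample(offmod, min(10, length(offmod)))
  })
  truth$true_term <- true_key
  truth$negative_term <- neg_key
  truth$realized_j <- realized
  list(collection = gene_set_collection(sets), truth = truth)
}

#' Generate the default synthetic fixture bundle
#'
#' The default study conditions: a 300-node scale-free interactome
#' (attachment 2), a planted 15-gene connected module with 3 exception
#' nodes, log2 shift `delta = 2` (all up-regulated) with noise `sigma =
#' 0.5` over 5 control and 5 treatment samples, and a GMT collection
#' holding the true pathway, one redundant decoy (J = 0.8), two crosstalk
#' decoys (J = 0.4 and 0.25), filler terms and a negative control.
#'
#' @param seed Integer seed (default 1).
#' @param n Interactome size (default 300).
#' @param module_size Planted module size (default 15).
#' @param n_exceptions Exception nodes in the module (default 3).
#' @param delta,sigma,n_ctrl,n_trt Expression simulation parameters.
#' @return List: `graph`, `expr`, `collection`, `truth`.
#' @export
simulate_fixture <- function(seed = 1, n = 300, module_size = 15,
                             n_exceptions = 3, delta = 2, sigma = 0.5,
                             n_ctrl = 5, n_trt = 5) {
  g <- simulate_interactome(n, attach = 2, seed = seed)
  truth <- plant_module(g, module_size, n_exceptions, seed = seed + 1)
  sim <- simulate_expression(g, truth, delta = delta, sigma = sigma,
                             n_ctrl = n_ctrl, n_trt = n_trt, prop_up = 1,
                             seed = seed + 2)
  # Decoy terms share genes drawn from the planted DE core (the part an
  # extractor recovers), so the Jaccard realized on the *enriched* gene
  # sets is c / core while the constructed full-set Jaccard is
  # c / (a + b - c) with a = module size. With the defaults (a = 15,
  # core = 12) this gives:
  #   redundant: shares 10, size 11 -> built J = 0.625, enriched J = 0.833
  #   crosstalk: shares  6, size  9 -> built J = 1/3,   enriched J = 0.5
  #   boundary:  shares  3, size  3 -> built J = 0.2,   enriched J = 0.25
  # (the last exercises the inclusive crosstalk boundary end-to-end)
  core <- module_size - n_exceptions
  stopifnot(core >= 6)
  a <- module_size
  c_r <- core - 2; b_r <- c_r + 1
  c_c <- ceiling(core / 2); b_c <- c_c + 3
  c_b <- max(3, round(core / 4)); b_b <- c_b
  spec <- data.frame(
    name = c("redundant decoy signaling", "crosstalk decoy signaling",
             "boundary crosstalk signaling"),
    size = c(b_r, b_c, b_b),
    j = c(c_r / (a + b_r - c_r), c_c / (a + b_c - c_c), c_b / (a + b_b - c_b)),
    stringsAsFactors = FALSE)
  gmt <- simulate_gmt(sim$truth, g, n_filler = 5, overlap_spec = spec,
                      seed = seed + 3)
  list(graph = g, expr = sim$expr, collection = gmt$collection,
       truth = gmt$truth)
}

#' Write a fixture bundle as standard pipeline inputs
#'
#' @param fx List from [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Writes `expression.tsv`,
#'   `samples.tsv`, `network.tsv`, `pathways.gmt`, `truth.json`.
#' @export
write_fixture_bundle <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- data.frame(gene = rownames(fx$expr$values), fx$expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ex, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$expr$sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(fx$graph, file.path(dir, "network.tsv"))
  gmt_lines <- vapply(names(fx$collection$sets), function(k) {
    paste(c(sub("^[^:]*::", "", k), "synthetic",
            fx$collection$sets[[k]]), collapse = "\t")
  }, "")
  writeLines(gmt_lines, file.path(dir, "pathways.gmt"))
  tr <- unclass(fx$truth)
  tr$sign <- as.list(tr$sign)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
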