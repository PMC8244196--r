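mk_rows <- function(sets, fdr = NULL) {
  if (is.null(fdr)) fdr <- rep(0.01, length(sets))
  data.frame(term = names(sets), db = "x", k = lengths(sets),
             K_term = lengths(sets), n_query = 20, N = 100,
             p_value = fdr, fdr = fdr,
             overlap_genes = vapply(sets, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}

test_that("jaccard evaluates the set-overlap formula", {
  expect_equal(jaccard(c("A", "B", "C", "D"), c("C", "D", "E", "F")), 1 / 3)
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(character(0), c("A")), 0)
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("jaccard distance satisfies the triangle inequality", {
  set.seed(31)
  pool <- sprintf("G%02d", 1:20)
  for (i in 1:500) {
    a <- sample(pool, sample(3:10, 1))
    b <- sample(pool, sample(3:10, 1))
    c <- sample(pool, sample(3:10, 1))
    dab <- 1 - jaccard(a, b); dbc <- 1 - jaccard(b, c); dac <- 1 - jaccard(a, c)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("redundancy collapse keeps the lowest-FDR representative", {
  sets <- list("x::X" = sprintf("G%d", 1:8),
               "x::Y" = sprintf("G%d", 1:7))  # J = 7/8 > 0.6
  rows <- mk_rows(sets, fdr = c(0.001, 0.01))
  out <- collapse_redundant(rows)
  expect_equal(out$representatives$term, "x::X")
  expect_equal(out$redundancy_map$representative[out$redundancy_map$member == "x::Y"],
               "x::X")
})

test_that("redundancy closes over chains via connected components", {
  # J(A,B) and J(B,C) high, J(A,C) low -> still a single family
  sets <- list("x::A" = sprintf("G%d", 1:10),
               "x::B" = sprintf("G%d", 3:12),
               "x::C" = sprintf("G%d", 5:14))
  stopifnot(jaccard(sets[[1]], sets[[2]]) > 0.6,
            jaccard(sets[[2]], sets[[3]]) > 0.6,
            jaccard(sets[[1]], sets[[3]]) <= 0.6)
  out <- collapse_redundant(mk_rows(sets, fdr = c(0.005, 0.01, 0.02)))
  expect_equal(nrow(out$representatives), 1)
  expect_equal(unique(out$redundancy_map$representative), "x::A")
})

test_that("redundancy uses strict and crosstalk inclusive thresholds", {
  # J exactly 0.55: both retained
  sets <- list("x::P" = sprintf("G%d", 1:20), "x::Q" = sprintf("G%d", 1:11))
  expect_equal(jaccard(sets[[1]], sets[[2]]), 0.55)
  expect_equal(nrow(collapse_redundant(mk_rows(sets))$representatives), 2)

  # J exactly 0.60 is not redundant (strict >), J = 0.25 is an edge (inclusive)
  s60 <- list("x::R" = sprintf("G%d", 1:5), "x::S" = sprintf("G%d", 3:5))
  expect_equal(jaccard(s60[[1]], s60[[2]]), 0.6)
  expect_equal(nrow(collapse_redundant(mk_rows(s60))$representatives), 2)

  s25 <- list("x::T" = sprintf("G%d", 1:6), "x::U" = c("G5", "G6", "X1", "X2"))
  expect_equal(jaccard(s25[[1]], s25[[2]]), 0.25)
  pg <- build_crosstalk_network(mk_rows(s25))
  expect_equal(nrow(pg$edges), 1)
  expect_equal(pg$edges$jaccard, 0.25)

  s20 <- list("x::V" = sprintf("G%d", 1:8), "x::W" = c("G1", "G2", "X1", "X2"))
  expect_equal(jaccard(s20[[1]], s20[[2]]), 0.2)
  expect_equal(nrow(build_crosstalk_network(mk_rows(s20))$edges), 0)
})

test_that("after collapse no representative pair exceeds the redundancy cutoff", {
  set.seed(17)
  pool <- sprintf("G%02d", 1:25)
  sets <- stats::setNames(lapply(1:12, function(i) sample(pool, sample(4:12, 1))),
                          sprintf("x::t%02d", 1:12))
  out <- collapse_redundant(mk_rows(sets))
  reps <- overlap_sets(out$representatives)
  if (length(reps) >= 2) {
    cmb <- utils::combn(length(reps), 2)
    jmax <- max(vapply(seq_len(ncol(cmb)), function(i) {
      jaccard(reps[[cmb[1, i]]], reps[[cmb[2, i]]])
    }, numeric(1)))
    expect_lte(jmax, 0.6)
  }
  # every input term is mapped to exactly one representative
  expect_setequal(out$redundancy_map$member, names(sets))
})

test_that("greedy modularity clustering recovers planted structure", {
  # two disjoint triangles
  sets <- list("x::A1" = c("G1", "G2", "G3", "G4"),
               "x::A2" = c("G2", "G3", "G4", "G5"),
               "x::A3" = c("G1", "G3", "G4", "G6"),
               "x::B1" = c("H1", "H2", "H3", "H4"),
               "x::B2" = c("H2", "H3", "H4", "H5"),
               "x::B3" = c("H1", "H3", "H4", "H6"))
  rows <- mk_rows(sets)
  pg <- cluster_pathways(build_crosstalk_network(rows, redundancy_cutoff = 1))
  expect_equal(length(unique(pg$clusters)), 2)
  expect_equal(length(unique(pg$clusters[paste0("x::A", 1:3)])), 1)

  # isolated nodes become singleton clusters
  iso <- mk_rows(list("x::i1" = "A", "x::i2" = "B", "x::i3" = "C",
                      "x::i4" = "D", "x::i5" = "E"))
  pg_iso <- cluster_pathways(build_crosstalk_network(iso))
  expect_equal(length(unique(pg_iso$clusters)), 5)
})

test_that("greedy modularity attains the exhaustive optimum on small graphs", {
  # two K4 blocks joined by a single bridge edge
  nodes <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  edges <- character(0)
  for (i in 1:3) for (j in (i + 1):4) {
    edges <- c(edges, sprintf("a%d", i), sprintf("a%d", j),
               sprintf("b%d", i), sprintf("b%d", j))
  }
  edges <- c(edges, "a1", "b1")
  g <- mk_g(edges)
  cl <- igraph::cluster_fast_greedy(g)
  q_greedy <- max(cl$modularity)
  expect_equal(q_greedy, max_modularity(g), tolerance = 1e-9)
  expect_equal(length(unique(igraph::membership(cl))), 2)

  # barbell of triangles and a star: greedy matches exhaustive optimum
  for (g2 in list(mk_g(c("A", "B", "B", "C", "A", "C",
                         "D", "E", "E", "F", "D", "F", "C", "D")),
                  mk_g(c("X", "L1", "X", "L2", "X", "L3")))) {
    cl2 <- igraph::cluster_fast_greedy(g2)
    expect_equal(max(cl2$modularity), max_modularity(g2), tolerance = 1e-9)
  }
})

test_that("cluster partition beats singletons and respects components", {
  set.seed(19)
  pool <- sprintf("G%02d", 1:30)
  sets <- stats::setNames(lapply(1:10, function(i) sample(pool, 8)),
                          sprintf("x::t%02d", 1:10))
  pg <- cluster_pathways(build_crosstalk_network(mk_rows(sets),
                                                 redundancy_cutoff = 1))
  ncomp <- igraph::components(pg$graph)$no
  expect_gte(length(unique(pg$clusters)), ncomp)
  if (igraph::ecount(pg$graph) > 0) {
    q <- igraph::modularity(pg$graph, pg$clusters[igraph::V(pg$graph)$name])
    q_singletons <- igraph::modularity(pg$graph, seq_len(igraph::vcount(pg$graph)))
    expect_gte(q, q_singletons)
  }
})
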