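test_that("bridge configurations respect the exception budget", {
  g <- mk_g(c("A", "B", "B", "C"))
  ind <- c(A = 1, B = 0, C = 1)
  sol1 <- greedy_max_subnetwork(g, ind, K = 1)
  expect_equal(sol1$nodes, c("A", "B", "C"))
  expect_equal(sol1$exceptions, "B")
  expect_equal(sol1$de_count, 2)

  sol0 <- greedy_max_subnetwork(g, ind, K = 0)
  expect_equal(sol0$nodes, "A")  # lexicographic tie over {A} vs {C}
  expect_equal(sol0$de_count, 1)
})

test_that("a hub exception unlocks all its leaves", {
  g <- mk_g(c("X", "L1", "X", "L2", "X", "L3", "X", "L4"))
  ind <- c(X = 0, L1 = 1, L2 = 1, L3 = 1, L4 = 1)
  sol <- greedy_max_subnetwork(g, ind, K = 1)
  expect_setequal(sol$nodes, c("X", "L1", "L2", "L3", "L4"))
  expect_equal(sol$de_count, 4)
  # exhaustive check agrees
  expect_equal(naive_best_subnetwork(g, ind, 1)$de, 4)
})

test_that("exact solver matches naive whole-subset enumeration", {
  for (seed in c(1, 2, 3)) {
    inst <- random_instance(12, 0.3, 0.35, seed = seed)
    for (K in 0:2) {
      ex <- exact_max_subnetwork(inst$g, inst$ind, K = K)
      nv <- naive_best_subnetwork(inst$g, inst$ind, K)
      expect_equal(ex$de_count, nv$de, info = sprintf("seed=%d K=%d", seed, K))
    }
  }
})

test_that("exact solver handles whole-graph and disconnected optima", {
  tri <- mk_g(c("A", "B", "B", "C", "A", "C"))
  sol <- exact_max_subnetwork(tri, c(A = 1, B = 1, C = 1), K = 0)
  expect_equal(sol$nodes, c("A", "B", "C"))
  expect_equal(sol$de_count, 3)

  two <- mk_g(c("A", "B", "C", "D"))
  sol2 <- exact_max_subnetwork(two, c(A = 1, B = 1, C = 1, D = 1), K = 0)
  expect_equal(sol2$nodes, c("A", "B"))  # lexicographic component choice

  big <- random_instance(25, 0.2, 0.3, seed = 1)
  expect_error(exact_max_subnetwork(big$g, big$ind, K = 1), "20 nodes")
})

test_that("greedy never beats exact and usually attains it", {
  n_eq <- 0; n_tot <- 0
  for (seed in 1:40) {
    inst <- random_instance(5 + seed %% 11, 0.3, 0.3, seed = 100 + seed)
    K <- seed %% 3
    gr <- greedy_max_subnetwork(inst$g, inst$ind, K = K)
    ex <- exact_max_subnetwork(inst$g, inst$ind, K = K)
    expect_lte(gr$de_count, ex$de_count)
    n_tot <- n_tot + 1
    n_eq <- n_eq + (gr$de_count == ex$de_count)
  }
  expect_gte(n_eq / n_tot, 0.8)
})

test_that("solutions are connected, within budget, and locally maximal", {
  for (seed in 1:10) {
    inst <- random_instance(14, 0.25, 0.4, seed = 200 + seed)
    sol <- greedy_max_subnetwork(inst$g, inst$ind, K = 2)
    if (!length(sol$nodes)) next
    sg <- igraph::induced_subgraph(inst$g, sol$nodes)
    expect_true(igraph::is_connected(sg))
    expect_lte(length(sol$exceptions), 2)
    # no adjacent indicator-1 node left out
    nb <- unique(unlist(igraph::adjacent_vertices(inst$g, sol$nodes)))
    nb_names <- igraph::V(inst$g)$name[nb]
    outside_ones <- setdiff(nb_names[inst$ind[nb_names] == 1], sol$nodes)
    expect_length(outside_ones, 0)
  }
})

test_that("de_count is monotone non-decreasing in K", {
  for (seed in 1:8) {
    inst <- random_instance(13, 0.3, 0.3, seed = 300 + seed)
    de_by_k <- vapply(0:3, function(K) {
      greedy_max_subnetwork(inst$g, inst$ind, K = K)$de_count
    }, numeric(1))
    expect_true(all(diff(de_by_k) >= 0))
  }
})

test_that("identical inputs give byte-identical solutions", {
  inst <- random_instance(15, 0.3, 0.4, seed = 77)
  s1 <- greedy_max_subnetwork(inst$g, inst$ind, K = 2)
  s2 <- greedy_max_subnetwork(inst$g, inst$ind, K = 2)
  expect_identical(s1, s2)
})

test_that("variant extraction nests directional solutions and reports counts", {
  # two regions: up-regulated left chain, down-regulated right chain,
  # joined through an indicator-0 hub
  g <- mk_g(c("U1", "U2", "U2", "H", "H", "D1", "D1", "D2"))
  de <- data.frame(gene = c("U1", "U2", "H", "D1", "D2"),
                   log2fc = c(2, 2, 0, -2, -2), t_stat = 0,
                   p_value = c(1e-5, 1e-5, 0.9, 1e-5, 1e-5),
                   fdr = c(1e-4, 1e-4, 0.9, 1e-4, 1e-4))
  ind <- binarize(de, fdr_cutoff = 0.01)
  sols <- extract_all_variants(g, ind, K = 1)
  expect_gte(sols$all$de_count, max(sols$up$de_count, sols$down$de_count))
  expect_setequal(sols$up$nodes[!(sols$up$nodes %in% sols$up$exceptions)],
                  c("U1", "U2"))
  expect_setequal(sols$down$nodes[!(sols$down$nodes %in% sols$down$exceptions)],
                  c("D1", "D2"))
  expect_equal(sols$all$de_count, 4)
  expect_equal(sols$summary$variant, c("all", "up", "down"))

  # K=0 on a fully indicator-1 graph returns the whole graph
  g2 <- mk_g(c("A", "B", "B", "C"))
  ind2 <- structure(list(all = c(A = 1L, B = 1L, C = 1L),
                         up = c(A = 1L, B = 1L, C = 1L),
                         down = c(A = 0L, B = 0L, C = 0L),
                         fc_cutoff = 2, fdr_cutoff = 0.005),
                    class = "indicator_set")
  sols2 <- extract_all_variants(g2, ind2, K = 0)
  expect_equal(sols2$all$nodes, c("A", "B", "C"))
  expect_equal(sols2$up$nodes, c("A", "B", "C"))
  expect_equal(sols2$down$de_count, 0)
})

test_that("planted-module fixtures are recovered by the greedy solver", {
  fx <- simulate_fixture(seed = 4)
  ind <- binarize(differential_expression(fx$expr))
  sol <- greedy_max_subnetwork(fx$graph, ind$all, K = 3)
  expect_gte(mean(fx$truth$de_genes %in% sol$nodes), 0.9)
  expect_lte(mean(!(sol$nodes %in% fx$truth$module)), 0.1)
})
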