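test_that("interactome generator yields a connected seeded scale-free graph", {
  g <- simulate_interactome(100, attach = 2, seed = 7)
  expect_equal(igraph::vcount(g), 100)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::V(g)$name[1:2], c("G0001", "G0002"))
  # attachment rule: close to 2 new edges per node after the seed
  expect_gte(igraph::ecount(g), 2 * 100 - 10)
  expect_lte(igraph::ecount(g), 2 * 100)

  g2 <- simulate_interactome(100, attach = 2, seed = 7)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  g3 <- simulate_interactome(100, attach = 2, seed = 8)
  expect_false(identical(igraph::as_edgelist(g), igraph::as_edgelist(g3)))

  expect_error(simulate_interactome(3, attach = 3), "n > attach")
})

test_that("planted modules are connected and exceptions removable", {
  g <- simulate_interactome(200, seed = 3)
  tr <- plant_module(g, size = 12, n_exceptions = 2, seed = 5)
  expect_length(tr$module, 12)
  expect_length(tr$exceptions, 2)
  expect_length(tr$de_genes, 10)
  expect_true(igraph::is_connected(igraph::induced_subgraph(g, tr$module)))
  # removing the exceptions keeps the DE part connected (recoverable core)
  expect_true(igraph::is_connected(igraph::induced_subgraph(g, tr$de_genes)))

  tr0 <- plant_module(g, size = 8, n_exceptions = 0, seed = 5)
  expect_equal(tr0$de_genes, tr0$module)

  expect_error(plant_module(g, size = 500), "exceeds")
})

test_that("expression simulation shifts planted genes by delta", {
  g <- simulate_interactome(150, seed = 11)
  tr <- plant_module(g, size = 10, n_exceptions = 2, seed = 11)
  sim <- simulate_expression(g, tr, delta = 2, sigma = 0.5, seed = 11)
  m <- sim$expr$values
  expect_equal(sim$expr$scale, "log2")
  lfc <- rowMeans(m[, 6:10]) - rowMeans(m[, 1:5])
  # planted DE genes: observed shift near +2 (all-up default)
  expect_equal(unname(mean(lfc[tr$de_genes])), 2, tolerance = 0.35)
  # exception genes and background carry no shift
  expect_lt(abs(mean(lfc[setdiff(rownames(m), tr$de_genes)])), 0.2)
  expect_true(all(sim$truth$sign[tr$de_genes] == 1))

  sim2 <- simulate_expression(g, tr, delta = 2, sigma = 0.5, seed = 11)
  expect_identical(sim$expr$values, sim2$expr$values)

  # expected moderated-t magnitude for planted genes ~ delta/(sigma*sqrt(2/5))
  de <- differential_expression(sim$expr)
  t_planted <- abs(de$t_stat[de$gene %in% tr$de_genes])
  expect_equal(mean(t_planted), 2 / (0.5 * sqrt(2 / 5)), tolerance = 0.35)
})

test_that("zero effect size leaves the pipeline without signal", {
  g <- simulate_interactome(150, seed = 13)
  tr <- plant_module(g, size = 10, n_exceptions = 0, seed = 13)
  sim <- simulate_expression(g, tr, delta = 0.001, sigma = 0.5, seed = 13)
  ind <- binarize(differential_expression(sim$expr))
  expect_equal(sum(ind$all), 0)
  expect_warning(sol <- greedy_max_subnetwork(g, ind$all, K = 3),
                 "no indicator-1")
  expect_equal(sol$de_count, 0)
})

test_that("GMT surgery realizes requested Jaccard values exactly", {
  g <- simulate_interactome(120, seed = 17)
  tr <- plant_module(g, size = 12, n_exceptions = 2, seed = 17)
  # a = 12: size 6 sharing 6 -> J = 0.5; c = J(a+b)/(1+J) = 6 exactly
  spec <- data.frame(name = "half signaling", size = 6, j = 0.5)
  out <- simulate_gmt(tr, g, n_filler = 3, overlap_spec = spec, seed = 17)
  sets <- out$collection$sets
  true_set <- sets[[out$truth$true_term]]
  expect_setequal(true_set, tr$module)
  expect_equal(jaccard(true_set, sets[["synthetic::half signaling"]]), 0.5)
  expect_equal(unname(out$truth$realized_j["synthetic::half signaling"]), 0.5)
  # negative term shares nothing with the module
  expect_length(intersect(sets[[out$truth$negative_term]], tr$module), 0)
  # every term name survives the keyword filter
  expect_true(all(grepl("signal", tolower(names(sets)))))
})

test_that("infeasible Jaccard targets fail with feasible size suggestions", {
  g <- simulate_interactome(60, seed = 19)
  tr <- plant_module(g, size = 8, n_exceptions = 0, seed = 19)
  # a = 8, b = 8, J = 0.25 -> c = 3.2, not an integer
  bad <- data.frame(name = "bad signaling", size = 8, j = 0.25)
  expect_error(simulate_gmt(tr, g, overlap_spec = bad, seed = 19),
               "c = J\\(a\\+b\\)/\\(1\\+J\\) = 3.2.*feasible")
  # a = 8, b = 12, J = 0.25 -> c = 4 works
  ok <- data.frame(name = "ok signaling", size = 12, j = 0.25)
  out <- simulate_gmt(tr, g, overlap_spec = ok, seed = 19)
  expect_equal(unname(out$truth$realized_j["synthetic::ok signaling"]), 0.25)
})

test_that("fixture bundles round-trip through the standard file formats", {
  fx <- simulate_fixture(seed = 2, n = 120, module_size = 10, n_exceptions = 2)
  dir <- tempfile()
  write_fixture_bundle(fx, dir)
  m <- read_expression(file.path(dir, "expression.tsv"),
                       file.path(dir, "samples.tsv"), scale = "log2")
  expect_equal(dim(m$values), dim(fx$expr$values))
  expect_equal(m$values, fx$expr$values, tolerance = 1e-9)
  g <- read_network(file.path(dir, "network.tsv"))
  expect_equal(igraph::vcount(g), igraph::vcount(fx$graph))
  expect_equal(igraph::ecount(g), igraph::ecount(fx$graph))
  coll <- read_gmt(file.path(dir, "pathways.gmt"), db = "synthetic")
  expect_setequal(names(coll$sets), names(fx$collection$sets))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(truth$module, fx$truth$module)
})
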