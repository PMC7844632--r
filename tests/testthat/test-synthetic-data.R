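test_that("preferential attachment with m = 1 yields a tree", {
  g <- generate_ppi_graph(5, attachment = 1, seed = 7)
  expect_equal(igraph::ecount(g), 4)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
})

test_that("attachment-2 graph on 100 nodes has the pinned edge count", {
  g <- generate_ppi_graph(100, attachment = 2, seed = 1)
  # node 2 can only attach once, nodes 3..100 attach twice: 1 + 2*98
  expect_equal(igraph::ecount(g), 197)
  expect_true(igraph::is_simple(g))
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::V(g)$name, paste0("g", 1:100))
})

test_that("graph generation rejects n_nodes <= attachment", {
  expect_error(generate_ppi_graph(2, attachment = 2, seed = 0), "exceed")
})

test_that("graphs are simple and undirected across seeds and models", {
  for (s in 1:8) {
    g <- generate_ppi_graph(40, attachment = 2, seed = s)
    expect_true(igraph::is_simple(g))
    expect_false(igraph::is_directed(g))
  }
  g <- generate_ppi_graph(40, attachment = 3, seed = 4, model = "erdos_renyi")
  expect_true(igraph::is_simple(g))
  expect_true(igraph::is_connected(g))
})

test_that("graph generation is deterministic given the seed", {
  g1 <- generate_ppi_graph(60, attachment = 2, seed = 11)
  g2 <- generate_ppi_graph(60, attachment = 2, seed = 11)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("planting a +2-bit shift on 4 genes scales each variance by 2", {
  study <- synthetic_study(n_genes = 4, n_stages = 4, samples_per_stage = 3,
                           attachment = 1, seed = 3)
  study <- plant_transition(study, delta_bits = 2, stage_index = 3)
  # c = 2^(2/4) so the variance scale is c^2 = 2
  expect_equal(diag(study$stages[[3]]$sigma), rep(2, 4))
  expect_equal(study$stages[[2]]$sigma, diag(4))
  tr <- true_entropy_trajectory(study)
  expect_equal(unname(tr[3] - tr[2]), 2, tolerance = 1e-12)
  expect_equal(unname(tr[4] - tr[3]), 0)
})

test_that("a zero-delta plant leaves all stages identical", {
  study <- plant_transition(synthetic_study(n_genes = 6, seed = 5,
                                            n_stages = 3,
                                            samples_per_stage = 3,
                                            attachment = 1),
                            delta_bits = 0, stage_index = 2)
  expect_equal(study$stages[[2]]$sigma, study$stages[[1]]$sigma)
  expect_equal(diff(unname(true_entropy_trajectory(study))), c(0, 0))
})

test_that("negative planted delta reproduces the closed-form difference", {
  study <- synthetic_study(n_genes = 5, n_stages = 3, samples_per_stage = 3,
                           base_sigma = diag(1:5), attachment = 1, seed = 9)
  study <- plant_transition(study, delta_bits = -3, stage_index = 2)
  h0 <- true_global_entropy(study$stages[[1]])
  h1 <- true_global_entropy(study$stages[[2]])
  expect_equal(h1 - h0, -3, tolerance = 1e-12)
})

test_that("plant_transition rejects the control stage and bad indices", {
  study <- synthetic_study(n_genes = 4, n_stages = 3, samples_per_stage = 2,
                           attachment = 1, seed = 1)
  expect_error(plant_transition(study, 1, stage_index = 1), "control")
  expect_error(plant_transition(study, 1, stage_index = 4))
})

test_that("planted delta is exact for random dimensions and deltas", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    delta <- runif(1, -4, 4)
    sigma <- random_pd(n)
    study <- synthetic_study(n_genes = n, n_stages = 3,
                             samples_per_stage = 2, base_sigma = sigma,
                             attachment = 1, seed = i)
    study <- plant_transition(study, delta, stage_index = 2)
    tr <- true_entropy_trajectory(study)
    expect_equal(unname(tr[2] - tr[1]), delta, tolerance = 1e-9)
  }
})

test_that("sampled expression has the right shape, labels, and manifest", {
  study <- synthetic_study(n_genes = 10, n_stages = 2, samples_per_stage = 3,
                           attachment = 1, seed = 2)
  drawn <- sample_expression(study)
  expect_equal(dim(drawn$expression), c(10, 6))
  expect_equal(rownames(drawn$expression), paste0("g", 1:10))
  expect_equal(as.vector(table(drawn$manifest$sample_to_stage)[
    drawn$manifest$stage_order]), c(3L, 3L))
  expect_equal(drawn$manifest$stage_order[1], "normal")
})

test_that("sampling is reproducible and stage streams are independent", {
  study <- synthetic_study(n_genes = 8, n_stages = 3, samples_per_stage = 3,
                           attachment = 1, seed = 77)
  a <- sample_expression(study)
  b <- sample_expression(study)
  expect_identical(a$expression, b$expression)
  # appending a stage must not perturb earlier stages' draws
  wider <- synthetic_study(n_genes = 8, n_stages = 4, samples_per_stage = 3,
                           graph = study$graph, seed = 77)
  w <- sample_expression(wider)
  expect_identical(w$expression[, 1:9], a$expression)
})

test_that("sample moments converge to the model at large n", {
  study <- synthetic_study(n_genes = 3, n_stages = 2,
                           samples_per_stage = c(1e5, 2),
                           mu = rep(0, 3), attachment = 1, seed = 123)
  drawn <- sample_expression(study)
  x <- stage_matrix(drawn$expression, drawn$manifest, "normal")
  expect_lt(max(abs(rowMeans(x))), 0.02)
  expect_lt(max(abs(apply(x, 1, var) - 1)), 0.02)
})

test_that("log-normal observations exponentiate the same normal draws", {
  norm <- synthetic_study(n_genes = 5, n_stages = 2, samples_per_stage = 4,
                          attachment = 1, seed = 31)
  logn <- synthetic_study(n_genes = 5, n_stages = 2, samples_per_stage = 4,
                          observation_model = "lognormal",
                          graph = norm$graph, seed = 31)
  a <- sample_expression(norm)$expression
  b <- sample_expression(logn)$expression
  expect_true(all(b > 0))
  expect_equal(log_transform(b), a, tolerance = 1e-12)
  # the log-normal model's reported true entropy is the underlying normal's
  expect_equal(true_global_entropy(logn$stages[[1]]),
               true_global_entropy(norm$stages[[1]]))
})

test_that("true_global_entropy matches the closed form on diagonals", {
  unit <- 0.5 * log2(2 * pi * exp(1))
  expect_equal(true_global_entropy(matrix(1)), unit, tolerance = 1e-12)
  expect_equal(true_global_entropy(diag(2)), 2 * unit, tolerance = 1e-12)
  expect_equal(true_global_entropy(diag(c(4, 1))), 2 * unit + 1,
               tolerance = 1e-12)
})

test_that("synthetic studies round-trip through plain-text files", {
  study <- plant_transition(
    synthetic_study(n_genes = 6, n_stages = 3, samples_per_stage = 3,
                    attachment = 1, seed = 8),
    delta_bits = 1.5, stage_index = 3)
  dir <- tempfile("study")
  write_synthetic_study(study, dir)
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_identical(expr, sample_expression(study)$expression)
  man <- read_sample_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$stage_order, c("normal", "stage_1", "stage_2"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$transition_stage_index, 3)
  expect_equal(truth$delta_bits, 1.5)
  expect_equal(truth$true_entropy_bits,
               unname(true_entropy_trajectory(study)))
  edges <- read_edge_list(file.path(dir, "edges.tsv"))
  expect_equal(nrow(edges), igraph::ecount(study$graph))
})
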