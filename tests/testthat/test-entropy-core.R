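unit_bits <- 0.5 * log2(2 * pi * exp(1))

test_that("sample covariance handles both orientations and ddof", {
  x <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))   # perfectly collinear genes
  cv <- sample_covariance(x, "genes_as_variables")
  expect_equal(unname(cv$K), matrix(c(1, 2, 2, 4), 2))
  expect_equal(cv$n_obs, 3)
  expect_equal(cv$n, 2)

  cv1 <- sample_covariance(matrix(c(0, 2), 1), "genes_as_variables")
  expect_equal(unname(cv1$K), matrix(2))

  sv <- sample_covariance(x, "samples_as_variables")
  expect_equal(dim(sv$K), c(3L, 3L))
  expect_equal(sv$n_obs, 2)

  cv0 <- sample_covariance(x, "genes_as_variables", ddof = 0)
  expect_equal(unname(cv0$K), matrix(c(1, 2, 2, 4), 2) * 2 / 3)

  expect_error(sample_covariance(matrix(1:3, 3), "genes_as_variables"),
               ">= 2 observations")
})

test_that("gaussian entropy matches closed forms in bits", {
  expect_equal(gaussian_entropy(matrix(1)), unit_bits, tolerance = 1e-12)
  expect_equal(gaussian_entropy(diag(3)), 3 * unit_bits, tolerance = 1e-12)
  expect_equal(gaussian_entropy(diag(c(4, 1))), 2 * unit_bits + 1,
               tolerance = 1e-12)
  # printed three-decimal reference values
  expect_equal(gaussian_entropy(matrix(1)), 2.047095, tolerance = 1e-6)
  expect_equal(gaussian_entropy(diag(3)), 6.141286, tolerance = 1e-5)
  # a concentrated variable has negative differential entropy
  expect_lt(gaussian_entropy(matrix(1e-4)), 0)
})

test_that("singular covariances raise an explicit error", {
  expect_error(gaussian_entropy(matrix(c(1, 1, 1, 1), 2)), "singular")
  expect_error(gaussian_entropy(matrix(c(1, 2, 2, 1), 2)), "singular")
  expect_error(as_cov_estimate(matrix(1:6, 2, 3)), "square")
})

test_that("ridge regularization makes the singular case finite", {
  K <- matrix(c(1, 1, 1, 1), 2)
  cv <- regularize(as_cov_estimate(K), 1e-6)
  # det((1+e)^2 - 1) = 2e + e^2
  expect_equal(unname(det(cv$K)), 2e-6 + 1e-12, tolerance = 1e-9)
  expect_equal(cv$ridge, 1e-6)
  h <- gaussian_entropy(cv)
  expect_true(is.finite(h))
  expect_equal(h, 2 * unit_bits + 0.5 * log2(2e-6 + 1e-12), tolerance = 1e-9)
  expect_error(regularize(as_cov_estimate(K), 0), "positive")
})

test_that("entropy under vanishing ridge converges to the exact value", {
  set.seed(4)
  K <- random_pd(4)
  h0 <- gaussian_entropy(K)
  for (r in 10^-(6:10)) {
    expect_equal(gaussian_entropy(regularize(as_cov_estimate(K), r)), h0,
                 tolerance = 1e-3)
  }
})

test_that("scaling all variables by c shifts entropy by n*log2(c)", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    K <- random_pd(n)
    cc <- runif(1, 0.2, 5)
    expect_equal(gaussian_entropy(cc^2 * K),
                 gaussian_entropy(K) + n * log2(cc), tolerance = 1e-8)
  }
})

test_that("entropy is permutation invariant and block additive", {
  set.seed(12)
  K <- random_pd(5)
  p <- sample(5)
  expect_equal(gaussian_entropy(K[p, p]), gaussian_entropy(K),
               tolerance = 1e-10)
  K2 <- random_pd(3)
  blk <- rbind(cbind(K, matrix(0, 5, 3)), cbind(matrix(0, 3, 5), K2))
  expect_equal(gaussian_entropy(blk),
               gaussian_entropy(K) + gaussian_entropy(K2), tolerance = 1e-9)
})

test_that("global entropy with samples as variables matches its oracle", {
  # 2 i.i.d. unit-normal samples observed across many genes: h -> 2 units
  study <- synthetic_study(n_genes = 3, n_stages = 2,
                           samples_per_stage = 2, seed = 1, attachment = 1)
  set.seed(99)
  expr <- matrix(rnorm(2e4 * 2), 2e4,
                 dimnames = list(paste0("g", 1:2e4), c("a", "b")))
  man <- sample_manifest(c("a", "b"), c("normal", "normal"))
  h <- global_expression_entropy(expr, rownames(expr), "normal", man)
  expect_equal(as.numeric(h), 2 * unit_bits, tolerance = 0.05)
  expect_equal(attr(h, "n"), 2)
  expect_equal(attr(h, "n_obs"), 2e4)
})

test_that("global entropy validates genes and stage membership", {
  m <- tiny_expr(); man <- tiny_manifest()
  expect_error(global_expression_entropy(m, c("g1", "gX"), "normal", man),
               "gX")
  expect_error(global_expression_entropy(m, "g1", "normal", man), ">= 2")
})

test_that("local entropy covers the 1-D case and the rank bound", {
  expr <- matrix(c(0, 2, 1, 3), 1, dimnames = list("g1", paste0("s", 1:4)))
  man <- sample_manifest(paste0("s", 1:4), rep(c("normal", "tumor"), each = 2))
  iso <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("g1")
  ln <- local_network(iso, "g1")
  h <- local_network_entropy(ln, expr, "normal", man)
  expect_equal(as.numeric(h), unit_bits + 0.5, tolerance = 1e-9)

  # more member genes than samples: genes-as-variables covariance is
  # rank deficient, so the error policy must trip
  study <- synthetic_study(n_genes = 10, n_stages = 2,
                           samples_per_stage = 3, seed = 21)
  drawn <- sample_expression(study)
  lns <- all_local_networks(study$graph, study$gene_ids)
  big <- Filter(function(l) length(l$members) > 3, lns)[[1]]
  expect_error(local_network_entropy(big, drawn$expression, "normal",
                                     drawn$manifest, singularity = "error"),
               "singular")
  dropped <- local_network_entropy(big, drawn$expression, "normal",
                                   drawn$manifest, singularity = "drop")
  expect_true(is.na(dropped))
  ridged <- local_network_entropy(big, drawn$expression, "normal",
                                  drawn$manifest, singularity = "ridge")
  expect_true(is.finite(ridged))
  expect_equal(attr(ridged, "ridge_used"), 1e-8)
})

test_that("local entropy converges for independent unit-variance genes", {
  study <- synthetic_study(n_genes = 3, n_stages = 2,
                           samples_per_stage = c(1e4, 2),
                           mu = rep(0, 3), attachment = 1, seed = 17)
  drawn <- sample_expression(study)
  g <- study$graph
  center <- names(which(igraph::degree(g) == 2))[1]
  ln <- local_network(g, center)   # 3 genes in a 3-node graph
  h <- local_network_entropy(ln, drawn$expression, "normal", drawn$manifest)
  expect_equal(as.numeric(h), 3 * unit_bits, tolerance = 0.05)
})

test_that("members without expression are dropped and recorded", {
  g <- toy_graph()
  expr <- matrix(rnorm(8), 2, dimnames = list(c("2", "5"), paste0("s", 1:4)))
  man <- sample_manifest(paste0("s", 1:4), rep(c("n", "t"), each = 2))
  ln <- local_network(g, "2")   # members 2,1,3,5 but only 2 and 5 measured
  h <- local_network_entropy(ln, expr, "n", man)
  expect_setequal(attr(h, "dropped_members"), c("1", "3"))
  expect_equal(attr(h, "n_used"), 2)
  bad <- local_network(g, "1")
  expr2 <- expr[c(2), , drop = FALSE]
  expect_error(local_network_entropy(bad, expr2, "n", man), "no member")
})

test_that("average network entropy flips the sign of the mean", {
  expect_equal(average_network_entropy(c(-1, -2, -3)), 2)
  expect_equal(average_network_entropy(c(5, 5)), -5)
  expect_equal(average_network_entropy(0), 0)
  expect_error(average_network_entropy(numeric(0)), "empty")
  expect_error(average_network_entropy(c(1, NA)), "non-finite")
})

test_that("stage profiles conserve H = -mean(local) exactly", {
  study <- synthetic_study(n_genes = 12, n_stages = 2,
                           samples_per_stage = 8, seed = 33, attachment = 1)
  drawn <- sample_expression(study)
  lns <- all_local_networks(study$graph, study$gene_ids)
  prof <- stage_entropy_profile(drawn$expression, drawn$manifest, "normal",
                                study$gene_ids, lns)
  expect_identical(prof$H, -mean(prof$local))
  expect_equal(prof$n_nodes, length(prof$local))
  expect_equal(prof$stage, "normal")
  expect_true(is.finite(prof$h_global))
})
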