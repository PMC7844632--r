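#' Generate a synthetic interactome graph
#'
#' Random simple, connected, undirected graph standing in for a curated
#' PPI network. The default preferential-attachment model yields the
#' heavy-tailed degree distribution characteristic of interactomes; an
#' Erdos-Renyi variant is available for null comparisons. Vertices are
#' named `g1 ... gN` so they double as gene identifiers.
#'
#' @param n_nodes Number of nodes (> `attachment`).
#' @param attachment Edges added per node in the preferential-attachment
#'   model (`m`); with `attachment = 1` the graph is a tree. For the
#'   Erdos-Renyi model it sets the expected degree `2 * attachment`.
#' @param seed Integer seed; the graph is deterministic given it.
#' @param model `"preferential_attachment"` (default) or `"erdos_renyi"`.
#' @return A named, simple, connected, undirected `igraph` graph.
#' @export
generate_ppi_graph <- function(n_nodes, attachment = 2, seed = 1,
                               model = c("preferential_attachment",
                                         "erdos_renyi")) {
  model <- match.arg(model)
  if (attachment < 1L) stop("attachment must be >= 1")
  if (n_nodes <= attachment) {
    stop("n_nodes must exceed attachment (got n_nodes = ", n_nodes,
         ", attachment = ", attachment, ")")
  }
  g <- with_seed(seed, {
    if (model == "preferential_attachment") {
      igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
    } else {
      p <- min(1, 2 * attachment / (n_nodes - 1))
      gg <- igraph::sample_gnp(n_nodes, p)
      tries <- 0L
      while (!igraph::is_connected(gg) && tries < 100L) {
        gg <- igraph::sample_gnp(n_nodes, p)
        tries <- tries + 1L
      }
      if (!igraph::is_connected(gg)) {
        stop("could not draw a connected Erdos-Renyi graph; increase attachment")
      }
      gg
    }
  })
  igraph::V(g)$name <- paste0("g", seq_len(n_nodes))
  g
}

#' One stage of a synthetic study
#'
#' A stage model is a multivariate normal (or base-2 log-normal) over the
#' study's genes: mean vector `mu` (log2 units), symmetric positive-definite
#' covariance `sigma` (log2 units squared), and an observation model. Under
#' `"lognormal"`, samples are `2^z` with `z` the normal draw, so a log2
#' transform of the observations recovers the normal model exactly.
#'
#' @param stage_label Stage name.
#' @param mu Mean vector.
#' @param sigma Covariance matrix (symmetric positive definite).
#' @param observation_model `"normal"` (default) or `"lognormal"`.
#' @return Object of class `synthetic_stage_model`.
#' @export
synthetic_stage_model <- function(stage_label, mu, sigma,
                                  observation_model = c("normal", "lognormal")) {
  observation_model <- match.arg(observation_model)
  sigma <- as.matrix(sigma)
  if (length(mu) != nrow(sigma)) stop("length(mu) must equal dim(sigma)")
  if (max(abs(sigma - t(sigma))) > 1e-10 * max(1, max(abs(sigma)))) {
    stop("sigma must be symmetric")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sigma must be positive definite (min eigenvalue ",
                         format(min(ev)), ")")
  structure(list(stage_label = as.character(stage_label), mu = mu,
                 sigma = sigma, observation_model = observation_model),
            class = "synthetic_stage_model")
}

#' Build a synthetic multi-stage expression study
#'
#' Defines an ordered set of disease stages (the first is the healthy
#' control) that initially share one base covariance, over genes that are
#' the nodes of a synthetic interactome. Use [plant_transition()] to insert
#' a ground-truth entropy shift and [sample_expression()] to draw data.
#'
#' Defaults emulate a small multi-stage carcinogenesis microarray study:
#' a handful of stages with single-digit samples per stage, unit-variance
#' log2 expression around a typical intensity of 8, and a scale-free
#' interactome over the genes.
#'
#' @param n_genes Number of genes, default 50.
#' @param n_stages Number of stages including the control, default 5.
#' @param samples_per_stage Samples per stage (scalar or length-`n_stages`
#'   vector, each >= 2), default 6.
#' @param base_sigma Base covariance shared by all stages; default identity.
#' @param mu Mean vector; default `rep(8, n_genes)` (log2 intensity units).
#' @param observation_model `"normal"` (default) or `"lognormal"`.
#' @param graph Interactome over the genes; default a
#'   [generate_ppi_graph()] preferential-attachment graph.
#' @param attachment Attachment parameter for the default graph, default 2.
#' @param seed Master seed; stage-level sampling streams are derived from
#'   it, so adding a stage does not perturb earlier stages.
#' @param stage_labels Stage names; default `normal, stage_1, ...`.
#' @return Object of class `synthetic_study`: list with `stages` (list of
#'   [synthetic_stage_model()]s), `graph`, `gene_ids`, `samples_per_stage`,
#'   `transition_stage_index` (NULL until planted), `seed`.
#' @export
synthetic_study <- function(n_genes = 50, n_stages = 5, samples_per_stage = 6,
                            base_sigma = NULL, mu = NULL,
                            observation_model = c("normal", "lognormal"),
                            graph = NULL, attachment = 2, seed = 1,
                            stage_labels = NULL) {
  observation_model <- match.arg(observation_model)
  if (n_stages < 2L) stop("need at least a control and one disease stage")
  if (length(samples_per_stage) == 1L) {
    samples_per_stage <- rep(samples_per_stage, n_stages)
  }
  if (length(samples_per_stage) != n_stages || any(samples_per_stage < 2L)) {
    stop("samples_per_stage must give >= 2 samples for each of the ",
         n_stages, " stages")
  }
  if (is.null(stage_labels)) {
    stage_labels <- c("normal", paste0("stage_", seq_len(n_stages - 1L)))
  }
  if (anyDuplicated(stage_labels) || length(stage_labels) != n_stages) {
    stop("stage_labels must be ", n_stages, " unique labels")
  }
  if (is.null(graph)) {
    graph <- generate_ppi_graph(n_genes, attachment = attachment,
                                seed = derive_seed(seed, 0L))
  }
  gene_ids <- igraph::V(graph)$name
  if (length(gene_ids) != n_genes) {
    stop("graph has ", length(gene_ids), " nodes but n_genes = ", n_genes)
  }
  if (is.null(base_sigma)) base_sigma <- diag(n_genes)
  if (is.null(mu)) mu <- rep(8, n_genes)
  stages <- lapply(stage_labels, function(lbl) {
    synthetic_stage_model(lbl, mu, base_sigma, observation_model)
  })
  structure(list(stages = stages, graph = graph, gene_ids = gene_ids,
                 samples_per_stage = as.integer(samples_per_stage),
                 transition_stage_index = NULL, seed = as.integer(seed)),
            class = "synthetic_study")
}

# deterministic per-stream sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + 1000003 * stream) %% 2147483647)
}

#' Plant a ground-truth entropy shift at one stage
#'
#' From `stage_index` onward every stage's covariance is scaled
#' isotropically so that the true global entropy changes by exactly
#' `delta_bits`: since `h(a * Sigma) = h(Sigma) + 0.5 * n * log2(a)`, each
#' variable's standard deviation is scaled by `c = 2^(delta_bits / n)` for
#' an `n`-gene model. Stages before `stage_index` keep the base covariance,
#' so the true entropy trajectory is a step function with a jump of
#' `delta_bits` at the transition.
#'
#' @param study A [synthetic_study()].
#' @param delta_bits Entropy change in bits (may be negative; 0 leaves all
#'   stages identical).
#' @param stage_index 1-based index of the first shifted stage
#'   (`2 <= stage_index <= n_stages`; the control is never shifted).
#' @return The study with scaled stage covariances and
#'   `transition_stage_index` set.
#' @export
plant_transition <- function(study, delta_bits, stage_index) {
  stopifnot(inherits(study, "synthetic_study"))
  k <- length(study$stages)
  if (stage_index <= 1L || stage_index > k) {
    stop("stage_index must be in 2..", k, " (the control is never shifted)")
  }
  n <- length(study$gene_ids)
  scale <- 2^(2 * delta_bits / n)   # variance scale c^2 with c = 2^(delta/n)
  for (i in seq(stage_index, k)) {
    m <- study$stages[[i]]
    study$stages[[i]] <- synthetic_stage_model(m$stage_label, m$mu,
                                               m$sigma * scale,
                                               m$observation_model)
  }
  study$transition_stage_index <- as.integer(stage_index)
  study$delta_bits <- delta_bits
  study
}

#' True Gaussian entropy of a stage model
#'
#' Closed-form differential entropy `0.5 * log2((2*pi*e)^n * |Sigma|)` of
#' the stage's true covariance, in bits. For the `"lognormal"` observation
#' model this is the entropy of the underlying normal - the quantity the
#' pipeline estimates after the log2 transform.
#'
#' @param model A [synthetic_stage_model()] or a covariance matrix.
#' @return Entropy in bits.
#' @export
true_global_entropy <- function(model) {
  sigma <- if (inherits(model, "synthetic_stage_model")) model$sigma else as.matrix(model)
  n <- nrow(sigma)
  0.5 * n * log2(2 * pi * exp(1)) + 0.5 * chol_log2_det(sigma, "true covariance")
}

#' True entropy trajectory of a synthetic study
#'
#' @param study A [synthetic_study()].
#' @return Named numeric vector, true entropy (bits) per stage in order.
#' @export
true_entropy_trajectory <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  vapply(study$stages, function(m) {
    stats::setNames(true_global_entropy(m), m$stage_label)
  }, 0)
}

#' Draw expression data from a synthetic study
#'
#' Draws `samples_per_stage[t]` independent gene vectors from each stage's
#' multivariate normal; under the `"lognormal"` observation model the draws
#' are exponentiated base 2. Each stage uses its own RNG stream derived
#' from the master seed, so the same study yields byte-identical data and
#' appending stages leaves earlier stages' draws unchanged.
#'
#' @param study A [synthetic_study()].
#' @return List with `expression` (genes x samples matrix; log2 scale for
#'   `"normal"`, raw scale for `"lognormal"`) and `manifest`
#'   (a [sample_manifest()]).
#' @export
sample_expression <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  blocks <- vector("list", length(study$stages))
  sample_ids <- character(0)
  stage_of <- character(0)
  for (t in seq_along(study$stages)) {
    m <- study$stages[[t]]
    ns <- study$samples_per_stage[t]
    draw <- with_seed(derive_seed(study$seed, t), {
      MASS::mvrnorm(n = ns, mu = m$mu, Sigma = m$sigma)
    })
    draw <- matrix(draw, nrow = ns)      # mvrnorm drops dims at n = 1 guard
    x <- t(draw)                          # genes x samples
    if (m$observation_model == "lognormal") x <- 2^x
    ids <- sprintf("%s_s%d", m$stage_label, seq_len(ns))
    colnames(x) <- ids
    rownames(x) <- study$gene_ids
    blocks[[t]] <- x
    sample_ids <- c(sample_ids, ids)
    stage_of <- c(stage_of, rep(m$stage_label, ns))
  }
  expr <- do.call(cbind, blocks)
  manifest <- sample_manifest(sample_ids, stage_of,
                              stage_order = vapply(study$stages,
                                                   `[[`, "", "stage_label"))
  list(expression = expr, manifest = manifest)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `expression.tsv` (genes x samples), `manifest.tsv`, `edges.tsv`
#' (the interactome edge list), and `truth.json` (stage labels, true
#' entropies, planted transition index and delta, seed) into `dir`.
#'
#' @param study A [synthetic_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  drawn <- sample_expression(study)
  write_expression_table(drawn$expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample_id = names(drawn$manifest$sample_to_stage),
               stage = unname(drawn$manifest$sample_to_stage)),
    file.path(dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  el <- igraph::as_edgelist(study$graph)
  utils::write.table(el, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- list(stage_order = vapply(study$stages, `[[`, "", "stage_label"),
                samples_per_stage = study$samples_per_stage,
                true_entropy_bits = unname(true_entropy_trajectory(study)),
                transition_stage_index = study$transition_stage_index,
                delta_bits = study$delta_bits,
                observation_model = study$stages[[1L]]$observation_model,
                seed = study$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic study:", length(x$gene_ids), "genes,",
      length(x$stages), "stages,",
      paste(x$samples_per_stage, collapse = "/"), "samples per stage\n")
  if (!is.null(x$transition_stage_index)) {
    cat(sprintf("  planted shift: %+.3f bits from stage %d ('%s')\n",
                x$delta_bits, x$transition_stage_index,
                x$stages[[x$transition_stage_index]]$stage_label))
  }
  invisible(x)
}
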