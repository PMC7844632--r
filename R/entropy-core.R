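#' Sample covariance of an expression slice
#'
#' Estimates the covariance matrix of one stage's expression. Two
#' orientations are supported, because the dimension the entropy is taken
#' over differs between the global and local analyses:
#' * `genes_as_variables`: variables are genes, observations are samples;
#'   `K` is genes x genes. Used for local-network entropies.
#' * `samples_as_variables`: variables are samples, observations are genes;
#'   `K` is samples x samples. Used for the global per-stage expression
#'   entropy, where the gene set is large and the sample count small.
#'
#' @param x Genes-by-samples numeric matrix (one stage's slice).
#' @param orientation `"genes_as_variables"` or `"samples_as_variables"`.
#' @param ddof Denominator degrees-of-freedom correction; 1 (default) gives
#'   the unbiased estimator `n_obs - 1`, 0 the maximum-likelihood one.
#' @return Object of class `cov_estimate`: list with `K`, `n` (dimension),
#'   `n_obs`, `orientation`, `ddof`, `ridge` (0 until [regularize()]).
#' @export
sample_covariance <- function(x,
                              orientation = c("genes_as_variables",
                                              "samples_as_variables"),
                              ddof = 1) {
  orientation <- match.arg(orientation)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  obs <- if (orientation == "genes_as_variables") t(x) else x
  n_obs <- nrow(obs)
  if (n_obs < 2L) stop("covariance needs >= 2 observations, got ", n_obs)
  K <- stats::cov(obs)
  if (ddof != 1) K <- K * (n_obs - 1) / (n_obs - ddof)
  structure(list(K = K, n = ncol(obs), n_obs = n_obs,
                 orientation = orientation, ddof = ddof, ridge = 0),
            class = "cov_estimate")
}

#' Ridge-regularize a covariance estimate
#'
#' Adds `ridge` to the diagonal of `K`, making a rank-deficient estimate
#' positive definite. The amount is recorded on the returned object so that
#' downstream reports can flag regularized entropies.
#'
#' @param cov A `cov_estimate` (or plain symmetric matrix).
#' @param ridge Positive real added to the diagonal.
#' @return The regularized `cov_estimate`.
#' @export
regularize <- function(cov, ridge) {
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge <= 0) {
    stop("ridge must be a single positive number")
  }
  cov <- as_cov_estimate(cov)
  cov$K <- cov$K + diag(ridge, cov$n)
  cov$ridge <- cov$ridge + ridge
  cov
}

as_cov_estimate <- function(cov) {
  if (inherits(cov, "cov_estimate")) return(cov)
  if (is.matrix(cov)) {
    if (nrow(cov) != ncol(cov) || max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
      stop("covariance matrix must be square and symmetric")
    }
    return(structure(list(K = cov, n = nrow(cov), n_obs = NA_integer_,
                          orientation = NA_character_, ddof = NA, ridge = 0),
                     class = "cov_estimate"))
  }
  stop("expected a cov_estimate or a numeric matrix")
}

# log2 determinant of a symmetric PD matrix via Cholesky; the sum of log2
# factor diagonals avoids determinant under/overflow at large dimension.
chol_log2_det <- function(K, context = "covariance") {
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R) || any(diag(R) <= 0)) {
    stop("singular or non-positive-definite ", context,
         " (dimension ", nrow(K), "); consider ridge regularization",
         call. = FALSE)
  }
  2 * sum(log2(diag(R)))
}

#' Differential entropy of a multivariate Gaussian, in bits
#'
#' Computes `h = 0.5 * log2((2*pi*e)^n * |K|)` for an n-dimensional normal
#' with covariance `K`. The log-determinant is evaluated through a Cholesky
#' factorization in log space, so large dimensions do not underflow.
#' Differential entropy can be negative (a tightly concentrated variable
#' has `|K|` well below 1).
#'
#' @param cov A `cov_estimate` from [sample_covariance()] (possibly
#'   [regularize()]d) or a plain symmetric positive-definite matrix.
#' @return Entropy in bits (plain numeric).
#' @examples
#' gaussian_entropy(diag(1))          # 0.5*log2(2*pi*e) = 2.047 bits
#' gaussian_entropy(diag(c(4, 1)))    # adds 0.5*log2(4) = 1 bit
#' @export
gaussian_entropy <- function(cov) {
  cov <- as_cov_estimate(cov)
  0.5 * cov$n * log2(2 * pi * exp(1)) + 0.5 * chol_log2_det(cov$K)
}

#' Global expression entropy of one stage
#'
#' Builds the stage's matrix over the selected genes and returns its
#' Gaussian differential entropy. With the default
#' `orientation = "samples_as_variables"` the covariance is samples x
#' samples with the selected genes as observations, so the entropy dimension
#' equals the stage's sample count - the only orientation that stays
#' nonsingular when (as is typical) genes far outnumber samples.
#'
#' When the selected gene set is smaller than the sample count the
#' samples-as-variables covariance is itself rank deficient; the
#' `singularity` policy then either raises a stage-tagged error (default)
#' or ridge-regularizes and flags the value.
#'
#' @param expr Genes-by-samples log2 expression matrix.
#' @param genes Selected gene ids (all must be rows of `expr`).
#' @param stage Stage label.
#' @param manifest A [sample_manifest()].
#' @param orientation Covariance orientation, see [sample_covariance()].
#' @param singularity `"error"` (default) or `"ridge"`.
#' @param ridge Diagonal load under the `"ridge"` policy, default 1e-8.
#' @param ddof Covariance denominator correction, default 1.
#' @return Entropy in bits, with attributes `stage`, `source = "global"`,
#'   `n` (dimension), `n_obs`, `orientation`, `ridge_used`.
#' @export
global_expression_entropy <- function(expr, genes, stage, manifest,
                                      orientation = "samples_as_variables",
                                      singularity = c("error", "ridge"),
                                      ridge = 1e-8, ddof = 1) {
  singularity <- match.arg(singularity)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    stop("selected gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  if (length(genes) < 2L) stop("need >= 2 selected genes")
  sub <- stage_matrix(expr, manifest, stage)[genes, , drop = FALSE]
  if (ncol(sub) < 2L) stop("stage '", stage, "' has fewer than 2 samples")
  cov <- sample_covariance(sub, orientation = orientation, ddof = ddof)
  ridge_used <- 0
  h <- tryCatch(gaussian_entropy(cov), error = function(e) NULL)
  if (is.null(h)) {
    if (singularity == "error") {
      stop("stage '", stage, "': singular covariance (", cov$n,
           " variables, ", cov$n_obs, " observations); ",
           "consider ridge regularization", call. = FALSE)
    }
    cov <- regularize(cov, ridge)
    ridge_used <- ridge
    h <- gaussian_entropy(cov)
  }
  structure(h, stage = stage, source = "global", n = cov$n,
            n_obs = cov$n_obs, orientation = orientation,
            ridge_used = ridge_used)
}

#' Entropy of one local network at one stage
#'
#' Restricts the expression matrix to the local network's member genes
#' (members without expression are dropped and recorded) and the stage's
#' samples, estimates the covariance with genes as variables by default,
#' and applies the Gaussian entropy. When the member count exceeds the
#' sample count the genes-as-variables covariance is rank deficient; the
#' `singularity` policy decides what happens:
#' `"ridge"` (default) adds `ridge` to the diagonal and flags the value,
#' `"error"` raises a singular-covariance error naming the center,
#' `"drop"` returns NA (the caller excludes the node).
#'
#' @param ln A [local_network()].
#' @param expr Genes-by-samples log2 expression matrix.
#' @param stage Stage label.
#' @param manifest A [sample_manifest()].
#' @param orientation Covariance orientation, default `"genes_as_variables"`.
#' @param singularity `"ridge"`, `"error"`, or `"drop"`.
#' @param ridge Diagonal load used under the `"ridge"` policy, default 1e-8.
#' @param ddof Covariance denominator correction, default 1.
#' @return Entropy in bits with attributes `center`, `stage`,
#'   `source = "local"`, `n_members`, `n_used`, `dropped_members`,
#'   `ridge_used`; NA under the `"drop"` policy on singularity.
#' @export
local_network_entropy <- function(ln, expr, stage, manifest,
                                  orientation = "genes_as_variables",
                                  singularity = c("ridge", "error", "drop"),
                                  ridge = 1e-8, ddof = 1) {
  singularity <- match.arg(singularity)
  stopifnot(inherits(ln, "local_network"))
  measured <- intersect(ln$members, rownames(expr))
  dropped <- setdiff(ln$members, measured)
  if (length(measured) == 0L) {
    stop("no member of local network '", ln$center,
         "' has expression data")
  }
  sub <- stage_matrix(expr, manifest, stage)[measured, , drop = FALSE]
  cov <- sample_covariance(sub, orientation = orientation, ddof = ddof)
  ridge_used <- 0
  h <- tryCatch(gaussian_entropy(cov), error = function(e) NULL)
  if (is.null(h)) {
    if (singularity == "error") {
      stop("singular covariance for local network '", ln$center,
           "' at stage '", stage, "' (", cov$n, " variables, ",
           cov$n_obs, " observations)", call. = FALSE)
    }
    if (singularity == "drop") {
      return(structure(NA_real_, center = ln$center, stage = stage,
                       source = "local", n_members = length(ln$members),
                       n_used = length(measured), dropped_members = dropped,
                       ridge_used = NA_real_))
    }
    cov <- regularize(cov, ridge)
    ridge_used <- ridge
    h <- gaussian_entropy(cov)
  }
  structure(h, center = ln$center, stage = stage, source = "local",
            n_members = length(ln$members), n_used = length(measured),
            dropped_members = dropped, ridge_used = ridge_used)
}

#' Average network entropy
#'
#' The negative mean of the local-network entropies at one stage,
#' `H(t) = -(1/n) * sum_i h_i(t)`. The sign flip makes the reported values
#' positive for the concentrated (|K| << 1) local covariances typical of
#' log2 expression data; units remain bits.
#'
#' @param local_entropies Numeric vector of local entropies `h_i` (bits).
#' @return `H` in bits.
#' @examples
#' average_network_entropy(c(-1, -2, -3))  # 2
#' @export
average_network_entropy <- function(local_entropies) {
  h <- as.numeric(local_entropies)
  if (length(h) == 0L) stop("empty local-entropy list")
  if (any(!is.finite(h))) stop("non-finite local entropies; drop them first")
  -mean(h)
}

#' Full entropy profile of one stage
#'
#' Computes the global expression entropy, every local-network entropy, and
#' the average network entropy `H` of one stage. Nodes whose local
#' covariance is singular under the `"drop"` policy are excluded from `H`
#' and listed; with the default `"ridge"` policy all nodes contribute and
#' the ridged ones are flagged.
#'
#' @inheritParams local_network_entropy
#' @param genes Selected gene ids (for the global entropy).
#' @param local_networks Named list of [local_network()]s.
#' @param orientation_global Orientation for the global entropy.
#' @param orientation_local Orientation for local entropies.
#' @return Object of class `stage_entropy_profile`: list with `stage`,
#'   `h_global`, `local` (named vector of `h_i`), `H`, `n_nodes`,
#'   `provenance` (orientations, ridged node ids, dropped node ids).
#' @export
stage_entropy_profile <- function(expr, manifest, stage, genes, local_networks,
                                  orientation_global = "samples_as_variables",
                                  orientation_local = "genes_as_variables",
                                  singularity = c("ridge", "error", "drop"),
                                  ridge = 1e-8, ddof = 1) {
  singularity <- match.arg(singularity)
  hg <- global_expression_entropy(expr, genes, stage, manifest,
                                  orientation = orientation_global,
                                  singularity = if (singularity == "error")
                                    "error" else "ridge",
                                  ridge = ridge, ddof = ddof)
  locals <- lapply(local_networks, local_network_entropy,
                   expr = expr, stage = stage, manifest = manifest,
                   orientation = orientation_local,
                   singularity = singularity, ridge = ridge, ddof = ddof)
  hv <- vapply(locals, as.numeric, 0)
  ridged <- names(locals)[vapply(locals, function(e) {
    r <- attr(e, "ridge_used"); !is.na(r) && r > 0
  }, TRUE)]
  kept <- is.finite(hv)
  local <- hv[kept]
  structure(list(stage = stage,
                 h_global = as.numeric(hg),
                 local = local,
                 H = average_network_entropy(local),
                 n_nodes = sum(kept),
                 provenance = list(orientation_global = orientation_global,
                                   orientation_local = orientation_local,
                                   ddof = ddof,
                                   singularity = singularity,
                                   ridge = ridge,
                                   global_ridged = isTRUE(attr(hg, "ridge_used") > 0),
                                   ridged_nodes = ridged,
                                   dropped_nodes = names(hv)[!kept])),
            class = "stage_entropy_profile")
}

#' @export
print.stage_entropy_profile <- function(x, ...) {
  cat(sprintf("stage '%s': h_global = %.4f bits, H = %.4f bits over %d local networks\n",
              x$stage, x$h_global, x$H, x$n_nodes))
  if (length(x$provenance$ridged_nodes) > 0L) {
    cat("  ridge-regularized:", length(x$provenance$ridged_nodes), "node(s)\n")
  }
  invisible(x)
}
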