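#' Per-gene Welch t-test between a stage and the control
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, vectorized over genes. Conventions for degenerate genes: both
#' groups constant with equal means gives p = 1 (no evidence); both groups
#' constant with different means gives p = 0 (the t statistic diverges).
#'
#' @param stage_values Numeric vector (one gene) or genes-by-samples matrix
#'   for the stage group.
#' @param control_values Vector or matrix for the control group, same genes.
#' @return Numeric vector of two-sided p-values, one per gene.
#' @export
welch_t_test <- function(stage_values, control_values) {
  x <- if (is.matrix(stage_values)) stage_values else matrix(stage_values, nrow = 1L)
  y <- if (is.matrix(control_values)) control_values else matrix(control_values, nrow = 1L)
  if (nrow(x) != nrow(y)) stop("stage and control must cover the same genes")
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) stop("welch_t_test needs >= 2 samples per group")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1L)
  vy <- rowSums((y - my)^2) / (ny - 1L)
  sx <- vx / nx; sy <- vy / ny
  se2 <- sx + sy
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / (sx^2 / (nx - 1L) + sy^2 / (ny - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  # both groups constant: se2 == 0 makes t and df NaN
  degen <- se2 == 0
  if (any(degen)) p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  unname(p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: with p-values sorted ascending,
#' `adj_(i) = min_(j >= i) min(1, m * p_(j) / j)`, returned in the input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Stage-versus-control differential expression
#'
#' For each non-control stage, computes per-gene log2 fold change and a
#' Welch t p-value against the control stage, BH-adjusts the p-values
#' within the comparison, and flags genes passing the double filter
#' (`adj_p < p_threshold` and `|log2_fc| > log2(fc_threshold)`).
#'
#' Fold change is computed on linear-scale group means by default: the log2
#' matrix is exponentiated, group means taken, and their ratio re-logged
#' (`fc_mode = "linear_means"`). `fc_mode = "log2_diff"` uses the difference
#' of log2 means instead.
#'
#' @param expr Genes-by-samples matrix on the log2 scale.
#' @param manifest A [sample_manifest()]; its first stage is the control.
#' @param stages Stages to test; default all non-control stages.
#' @param p_threshold Adjusted-p cutoff of the double filter, default 0.05.
#' @param fc_threshold Fold-change cutoff (linear scale), default 1.5.
#' @param fc_mode `"linear_means"` (default) or `"log2_diff"`.
#' @return A data.frame of class `differential_records` with columns
#'   `gene_id`, `stage`, `log2_fc`, `p_value`, `adj_p`, `passes`.
#' @export
differential_expression <- function(expr, manifest,
                                    stages = NULL,
                                    p_threshold = 0.05, fc_threshold = 1.5,
                                    fc_mode = c("linear_means", "log2_diff")) {
  fc_mode <- match.arg(fc_mode)
  validate_expression_matrix(expr)
  control <- manifest$stage_order[1L]
  if (is.null(stages)) stages <- setdiff(manifest$stage_order, control)
  if (length(stages) == 0L) stop("no non-control stage to test")
  ctrl <- stage_matrix(expr, manifest, control)
  out <- lapply(stages, function(st) {
    x <- stage_matrix(expr, manifest, st)
    lfc <- switch(fc_mode,
      linear_means = log2(rowMeans(2^x) / rowMeans(2^ctrl)),
      log2_diff    = rowMeans(x) - rowMeans(ctrl))
    p <- welch_t_test(x, ctrl)
    adj <- bh_adjust(p)
    data.frame(gene_id = rownames(expr), stage = st,
               log2_fc = unname(lfc), p_value = p, adj_p = adj,
               passes = adj < p_threshold & abs(lfc) > log2(fc_threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("differential_records", "data.frame")
  attr(res, "p_threshold") <- p_threshold
  attr(res, "fc_threshold") <- fc_threshold
  res
}

#' Double-filter gene selection
#'
#' Selects the genes that pass both legs of the differential-expression
#' filter: BH-adjusted p-value below `p_threshold` and absolute fold change
#' above `fc_threshold` (two-sided, i.e. `|log2_fc| > log2(fc_threshold)`).
#' With `direction = "up"` or `"down"` only one sign of change qualifies.
#'
#' @param records Data frame with columns `gene_id`, `adj_p`, `log2_fc`
#'   (e.g. from [differential_expression()]).
#' @param p_threshold Adjusted-p cutoff, default 0.05.
#' @param fc_threshold Linear fold-change cutoff, default 1.5.
#' @param direction `"both"` (default), `"up"`, or `"down"`.
#' @return Character vector of selected gene ids, unique, in input order.
#' @export
double_filter <- function(records, p_threshold = 0.05, fc_threshold = 1.5,
                          direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "adj_p", "log2_fc") %in% names(records)))
  lfc_cut <- log2(fc_threshold)
  fc_ok <- switch(direction,
                  both = abs(records$log2_fc) > lfc_cut,
                  up   = records$log2_fc > lfc_cut,
                  down = records$log2_fc < -lfc_cut)
  sel <- records$gene_id[records$adj_p < p_threshold & fc_ok]
  unique(sel)
}

#' Combine per-stage gene selections into the study gene set
#'
#' The entropy matrices of every stage are built over a single common gene
#' set; by default that set is the union of the stage-versus-control
#' selections, so per-stage covariance matrices share their variables.
#' `mode = "per_stage"` returns the stage-specific sets unchanged.
#'
#' @param per_stage_selected Named list of character vectors, one per stage.
#' @param mode `"union"` (default) or `"per_stage"`.
#' @return Character vector (union) or the input list (per_stage).
#' @export
select_study_genes <- function(per_stage_selected, mode = c("union", "per_stage")) {
  mode <- match.arg(mode)
  if (length(per_stage_selected) == 0L) stop("no stage selections supplied")
  if (mode == "per_stage") return(per_stage_selected)
  genes <- unique(unlist(per_stage_selected, use.names = FALSE))
  if (length(genes) == 0L) {
    stop("double filter selected no genes in any stage; ",
         "consider relaxing p_threshold or fc_threshold")
  }
  genes
}
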