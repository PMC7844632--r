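#' Read a genes-by-samples expression table
#'
#' Reads a delimited text table whose first row holds sample identifiers and
#' whose first column holds gene identifiers, and returns a validated numeric
#' matrix (genes as rows, samples as columns). Values are expected on the
#' scale the caller says they are on; see [log_transform()] to move raw
#' intensities onto the log2 scale assumed by the entropy model.
#'
#' Duplicate gene rows (multiple probes per gene is the common microarray
#' case) are collapsed according to `duplicate_policy`, with a warning that
#' lists the collapsed identifiers. Missing or non-numeric cells are an
#' error, not imputed: covariance determinants are sensitive to imputation
#' and no imputation rule is part of the model.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator, default tab.
#' @param duplicate_policy How to collapse duplicated gene rows:
#'   `"mean"` (default), `"max"` (row with the largest mean), or `"first"`.
#' @return A numeric matrix with unique row (gene) and column (sample) names.
#' @seealso [write_expression_table()], [read_sample_manifest()]
#' @export
read_expression_table <- function(path, delimiter = "\t",
                                  duplicate_policy = c("mean", "max", "first")) {
  duplicate_policy <- match.arg(duplicate_policy)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty expression table: need at least one gene row and one sample column")
  }
  gene_ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], colnames(raw)[bad[2L]]))
  }
  dimnames(vals) <- list(gene_ids, colnames(raw))
  vals <- collapse_duplicate_genes(vals, duplicate_policy)
  validate_expression_matrix(vals)
  vals
}

collapse_duplicate_genes <- function(m, policy) {
  ids <- rownames(m)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) == 0L) return(m)
  warning(sprintf("collapsed %d duplicated gene id(s) by '%s': %s",
                  length(dup), policy, paste(dup, collapse = ", ")))
  keep_order <- unique(ids)
  rows <- lapply(keep_order, function(g) {
    block <- m[ids == g, , drop = FALSE]
    if (nrow(block) == 1L) return(block[1L, ])
    switch(policy,
           mean  = colMeans(block),
           max   = block[which.max(rowMeans(block)), ],
           first = block[1L, ])
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(keep_order, colnames(m))
  out
}

validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_table()]. Values are written with 17
#' significant digits so that a write/read round trip reproduces the doubles
#' bit-identically.
#'
#' @param m Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, delimiter = "\t") {
  validate_expression_matrix(m)
  txt <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(gene_id = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample-to-stage manifest
#'
#' A manifest maps each sample to its disease stage and fixes the stage
#' order; the first stage in `stage_order` is the control (healthy) state
#' against which differential expression and Wilcoxon comparisons are run.
#' Every stage must contain at least two samples, the minimum for a
#' covariance estimate.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param stage_labels Character vector, same length, stage of each sample.
#' @param stage_order Optional character vector fixing the stage order;
#'   defaults to order of first appearance in `stage_labels`.
#' @return An object of class `sample_manifest` with elements
#'   `sample_to_stage` (named character vector) and `stage_order`.
#' @export
sample_manifest <- function(sample_ids, stage_labels, stage_order = NULL) {
  sample_ids <- as.character(sample_ids)
  stage_labels <- as.character(stage_labels)
  if (length(sample_ids) != length(stage_labels)) {
    stop("sample_ids and stage_labels must have equal length")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in manifest")
  if (is.null(stage_order)) stage_order <- unique(stage_labels)
  if (anyDuplicated(stage_order)) stop("duplicate labels in stage_order")
  unknown <- setdiff(stage_labels, stage_order)
  if (length(unknown) > 0L) {
    stop("samples reference stage(s) not in stage_order: ",
         paste(unknown, collapse = ", "))
  }
  counts <- table(factor(stage_labels, levels = stage_order))
  if (any(counts < 2L)) {
    stop("every stage needs >= 2 samples; offending stage(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  s2s <- stats::setNames(stage_labels, sample_ids)
  structure(list(sample_to_stage = s2s, stage_order = stage_order),
            class = "sample_manifest")
}

#' Read a sample manifest from delimited text
#'
#' Expects a header line and two columns: `sample_id` and `stage`. The stage
#' order is taken from first appearance unless `stage_order` is supplied;
#' the first stage is the control.
#'
#' @param path Path to the manifest file.
#' @param delimiter Field separator, default tab.
#' @param stage_order Optional explicit stage order.
#' @return A [sample_manifest()] object.
#' @export
read_sample_manifest <- function(path, delimiter = "\t", stage_order = NULL) {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("manifest needs two columns: sample_id, stage")
  sample_manifest(df[[1L]], df[[2L]], stage_order = stage_order)
}

#' @export
print.sample_manifest <- function(x, ...) {
  counts <- table(factor(x$sample_to_stage, levels = x$stage_order))
  cat("sample manifest:", length(x$sample_to_stage), "samples,",
      length(x$stage_order), "stages (control =", x$stage_order[1L], ")\n")
  print(counts)
  invisible(x)
}

#' Samples belonging to a stage
#'
#' @param manifest A [sample_manifest()].
#' @param stage Stage label.
#' @return Character vector of sample ids.
#' @export
stage_samples <- function(manifest, stage) {
  stopifnot(inherits(manifest, "sample_manifest"))
  if (!stage %in% manifest$stage_order) {
    stop("unknown stage: ", stage)
  }
  names(manifest$sample_to_stage)[manifest$sample_to_stage == stage]
}

#' Expression submatrix of one stage
#'
#' Subsets the columns of an expression matrix to the samples of one stage,
#' preserving gene (row) order. Samples listed in the manifest but absent
#' from the matrix are an error (the join is where manifest/matrix mismatch
#' is detected).
#'
#' @param expr Genes-by-samples matrix.
#' @param manifest A [sample_manifest()].
#' @param stage Stage label.
#' @return Genes-by-samples matrix restricted to the stage's samples.
#' @export
stage_matrix <- function(expr, manifest, stage) {
  validate_expression_matrix(expr)
  ids <- stage_samples(manifest, stage)
  missing <- setdiff(ids, colnames(expr))
  if (length(missing) > 0L) {
    stop("manifest sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  expr[, ids, drop = FALSE]
}

#' Log-transform an expression matrix
#'
#' Elementwise `log(value + offset)` in the given base (default 2). Puts
#' raw-scale (log-normal) intensities onto the normal scale assumed by the
#' Gaussian entropy model. The transform is not assumed idempotent: the
#' caller tracks which scale a matrix is on.
#'
#' @param m Numeric matrix.
#' @param base Logarithm base, default 2.
#' @param offset Small nonnegative constant added before the log, default 0.
#' @return Transformed matrix, same dimnames.
#' @export
log_transform <- function(m, base = 2, offset = 0) {
  if (any(m + offset <= 0)) {
    stop("log_transform: nonpositive value(s) after adding offset ", offset)
  }
  out <- log(m + offset, base = base)
  dimnames(out) <- dimnames(m)
  out
}
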