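#' Entropy trajectory across stages
#'
#' Orders the per-stage entropy profiles by the manifest's stage order and
#' returns the two series the analysis tracks: the global expression
#' entropy `h_global` and the average network entropy `H`.
#'
#' @param profiles List of [stage_entropy_profile()]s covering every stage.
#' @param manifest A [sample_manifest()] fixing the stage order.
#' @return Data.frame of class `entropy_trajectory` with columns `stage`,
#'   `h_global`, `H`, one row per stage in order.
#' @export
entropy_trajectory <- function(profiles, manifest) {
  stages <- vapply(profiles, `[[`, "", "stage")
  missing <- setdiff(manifest$stage_order, stages)
  if (length(missing) > 0L) {
    stop("missing profile(s) for stage(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(manifest$stage_order, stages)
  out <- data.frame(stage = manifest$stage_order,
                    h_global = vapply(profiles[idx], `[[`, 0, "h_global"),
                    H = vapply(profiles[idx], `[[`, 0, "H"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("entropy_trajectory", "data.frame")
  out
}

#' Flag the largest consecutive entropy change
#'
#' Operationalizes the "sudden change" read off the stage trajectory: the
#' consecutive stage pair with the largest absolute difference in the
#' chosen series, ties broken by the earliest pair. A constant series is
#' flagged `no_change`. An alternative detector scores each step as a
#' z-score against the mean and standard deviation of the preceding steps
#' (`method = "zscore"`; needs >= 3 stages, falls back to the maximum
#' absolute difference when the preceding spread is zero).
#'
#' @param trajectory An [entropy_trajectory()] data.frame, or a plain
#'   numeric vector of stage values (optionally named by stage).
#' @param series `"global"` or `"network"` - which column to scan when a
#'   trajectory data.frame is given.
#' @param method `"max_abs_diff"` (default) or `"zscore"`.
#' @return List with `index` (the flagged pair is stages `index` ->
#'   `index + 1`), `from_stage`, `to_stage`, `delta` (signed), `no_change`.
#' @export
detect_sudden_change <- function(trajectory, series = c("global", "network"),
                                 method = c("max_abs_diff", "zscore")) {
  series <- match.arg(series)
  method <- match.arg(method)
  if (is.data.frame(trajectory)) {
    values <- if (series == "global") trajectory$h_global else trajectory$H
    labels <- trajectory$stage
  } else {
    values <- as.numeric(trajectory)
    labels <- names(trajectory)
    if (is.null(labels)) labels <- as.character(seq_along(values))
  }
  if (length(values) < 2L) stop("trajectory needs at least 2 stages")
  d <- diff(values)
  score <- abs(d)
  if (method == "zscore" && length(d) >= 3L) {
    z <- rep(NA_real_, length(d))
    for (i in 2:length(d)) {
      prev <- d[seq_len(i - 1L)]
      s <- stats::sd(prev)
      z[i] <- if (i >= 3L && s > 0) abs(d[i] - mean(prev)) / s else NA_real_
    }
    if (any(is.finite(z))) score <- ifelse(is.finite(z), z, -Inf)
  }
  i <- which.max(score)   # first maximum: earliest-pair tie-break
  list(index = i,
       from_stage = labels[i],
       to_stage = labels[i + 1L],
       delta = d[i],
       no_change = all(d == 0))
}

#' Healthy-anchored entropy groups
#'
#' Bins the local-network entropies of the healthy (control) stage into
#' contiguous half-open intervals `[origin + k*w, origin + (k+1)*w)` of
#' width `w`, anchored at `origin` (0 by default: the grid starts at the
#' zero unit regardless of where the healthy values lie). Bins extend to
#' negative indices when entropies fall below the origin - differential
#' entropies can be negative. These healthy-built groups are then held
#' fixed across all disease stages; only the entropy values move.
#'
#' @param healthy_locals Named numeric vector: local entropy per node in
#'   the healthy stage.
#' @param bin_width Positive bin width in bits.
#' @param origin Grid anchor, default 0.
#' @return Object of class `entropy_groups`: list with `bin_width`,
#'   `origin`, `bins` (data.frame `index`, `lower`, `upper`), and
#'   `node_to_bin` (named integer vector for the healthy stage).
#' @export
build_entropy_groups <- function(healthy_locals, bin_width, origin = 0) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a single positive number")
  }
  h <- healthy_locals
  if (length(h) == 0L || is.null(names(h))) {
    stop("healthy_locals must be a non-empty named vector")
  }
  idx <- bin_index_raw(h, origin, bin_width)
  lo <- min(idx); hi <- max(idx)
  bins <- data.frame(index = lo:hi,
                     lower = origin + (lo:hi) * bin_width,
                     upper = origin + (lo:hi + 1L) * bin_width)
  structure(list(bin_width = bin_width, origin = origin, bins = bins,
                 node_to_bin = idx),
            class = "entropy_groups")
}

bin_index_raw <- function(h, origin, width) {
  idx <- as.integer(floor((h - origin) / width))
  names(idx) <- names(h)
  idx
}

#' Bin index of entropy values under fixed groups
#'
#' Applies the healthy-anchored floor rule
#' `floor((h - origin) / bin_width)` of an existing [build_entropy_groups()]
#' grid to new entropy values (indices outside the healthy range are legal:
#' the grid is conceptually unbounded).
#'
#' @param groups An `entropy_groups` object.
#' @param h Numeric vector of entropies (named by node).
#' @return Integer bin indices, named like `h`.
#' @export
bin_index <- function(groups, h) {
  stopifnot(inherits(groups, "entropy_groups"))
  bin_index_raw(h, groups$origin, groups$bin_width)
}

#' @export
print.entropy_groups <- function(x, ...) {
  cat(sprintf("entropy groups: %d bins of width %g anchored at %g, %d nodes\n",
              nrow(x$bins), x$bin_width, x$origin, length(x$node_to_bin)))
  invisible(x)
}

#' Transition genes between two stages
#'
#' A transition gene is a node whose local-network entropy moves to a
#' different (healthy-anchored) entropy group between two stages - the
#' "color change" read off the stage-by-stage network renderings. The bin
#' grid is fixed from the healthy stage; only the entropy values move.
#'
#' @param groups [build_entropy_groups()] output (defines grid and node
#'   universe).
#' @param locals_from Named vector of local entropies at the earlier stage,
#'   or a [stage_entropy_profile()].
#' @param locals_to Same for the later stage.
#' @param stage_pair Optional character vector of length 2 naming the
#'   stages (taken from profiles when those are passed).
#' @return Data.frame of class `transition_report` with columns `gene`,
#'   `h_from`, `h_to`, `bin_from`, `bin_to`, one row per gene whose bin
#'   changed; `stage_pair` attached as an attribute.
#' @export
detect_transition_genes <- function(groups, locals_from, locals_to,
                                    stage_pair = NULL) {
  stopifnot(inherits(groups, "entropy_groups"))
  pull <- function(x) {
    if (inherits(x, "stage_entropy_profile")) {
      list(h = x$local, stage = x$stage)
    } else {
      list(h = x, stage = NA_character_)
    }
  }
  from <- pull(locals_from); to <- pull(locals_to)
  if (is.null(stage_pair)) stage_pair <- c(from$stage, to$stage)
  universe <- names(groups$node_to_bin)
  if (!setequal(names(from$h), universe) || !setequal(names(to$h), universe)) {
    stop("node universe mismatch between entropy groups and stage profiles")
  }
  hf <- from$h[universe]; ht <- to$h[universe]
  bf <- bin_index(groups, hf); bt <- bin_index(groups, ht)
  changed <- bf != bt
  out <- data.frame(gene = universe[changed],
                    h_from = unname(hf[changed]), h_to = unname(ht[changed]),
                    bin_from = unname(bf[changed]), bin_to = unname(bt[changed]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "stage_pair") <- stage_pair
  class(out) <- c("transition_report", "data.frame")
  out
}

#' Wilcoxon rank-sum comparison of local entropies
#'
#' Two-sided rank-sum (Mann-Whitney) test of a stage's local-network
#' entropies against the control's. The exact null distribution is
#' enumerated when both groups have at most 10 values and there are no
#' ties; otherwise the normal approximation with tie correction and
#' (optionally) continuity correction is used.
#'
#' @param stage_locals Numeric vector of local entropies at the stage.
#' @param control_locals Numeric vector for the control stage.
#' @param continuity_correction Apply the continuity correction in the
#'   normal approximation, default TRUE.
#' @return Object of class `stage_comparison`: list with `statistic` (the
#'   Mann-Whitney W), `p_value`, `n_stage`, `n_control`, `exact`.
#' @export
wilcoxon_compare <- function(stage_locals, control_locals,
                             continuity_correction = TRUE) {
  x <- as.numeric(stage_locals); y <- as.numeric(control_locals)
  if (length(x) == 0L || length(y) == 0L) stop("empty entropy list")
  exact <- length(x) <= 10L && length(y) <= 10L && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = continuity_correction)
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_stage = length(x), n_control = length(y),
                 exact = exact),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation",
              x$n_stage, x$n_control))
  invisible(x)
}

#' Normal versus log-normal distribution check
#'
#' The Gaussian entropy model assumes log2 expression is (multivariate)
#' normal, i.e. raw intensities are normal or log-normal. This check runs a
#' Lilliefors-type Kolmogorov-Smirnov test (parameters estimated from the
#' data) on the values as given (normal candidate) and on their log2
#' (log-normal candidate), and labels the candidate with the larger p-value
#' the better fit.
#'
#' @param values Numeric vector (>= 8 finite values; all positive when the
#'   log-normal candidate is evaluated).
#' @param candidates Which candidates to test; default both.
#' @return List with `results` (data.frame `candidate`, `statistic`, `p`)
#'   and `best_fit` (label of the larger-p candidate).
#' @export
distribution_check <- function(values,
                               candidates = c("normal", "lognormal")) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  v <- values[is.finite(values)]
  if (length(v) < 8L) stop("need >= 8 finite values (Lilliefors minimum plus margin)")
  rows <- lapply(candidates, function(cand) {
    z <- if (cand == "lognormal") {
      if (any(v <= 0)) stop("log-normal candidate requires positive values")
      log2(v)
    } else {
      v
    }
    lt <- nortest::lillie.test(z)
    data.frame(candidate = cand, statistic = unname(lt$statistic),
               p = lt$p.value, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(results = results,
       best_fit = results$candidate[which.max(results$p)])
}

#' Median, interquartile range, and standard error
#'
#' Descriptive statistics reported alongside the average network entropy:
#' median, IQR with linear-interpolation quantiles (R's default type 7),
#' and standard error `sd / sqrt(n)`. A single value has IQR 0 and SE 0 by
#' convention.
#'
#' @param h Numeric vector of entropies.
#' @return List with `median`, `iqr`, `se`, `n`.
#' @export
summarize_entropy <- function(h) {
  h <- as.numeric(h)
  if (length(h) == 0L) stop("empty entropy list")
  if (length(h) == 1L) {
    return(list(median = h, iqr = 0, se = 0, n = 1L))
  }
  list(median = stats::median(h),
       iqr = stats::IQR(h, type = 7),
       se = stats::sd(h) / sqrt(length(h)),
       n = length(h))
}

#' Run the full entropy pipeline on one study
#'
#' Orchestrates the end-to-end analysis: stage-versus-control differential
#' expression and double-filter selection -> interactome cleanup and gene
#' mapping -> first-neighbor local networks -> per-stage global, local and
#' average network entropies -> stage trajectory with sudden-change flags
#' for both series -> healthy-anchored entropy groups -> transition genes
#' for consecutive stage pairs -> Wilcoxon comparison of each stage's local
#' entropies against the control -> per-stage descriptive summaries.
#' Deterministic given its inputs.
#'
#' @param expr Genes-by-samples expression matrix on the log2 scale (apply
#'   [log_transform()] first for raw intensities).
#' @param manifest A [sample_manifest()]; first stage is the control.
#' @param graph Interactome: a cleaned `igraph`, or raw edge records (as
#'   from [read_edge_list()]) cleaned here via [clean_graph()].
#' @param id_map Optional gene-to-protein table for [map_selected_genes()].
#' @param keep_taxon Optional taxon filter applied when `graph` is raw
#'   records.
#' @param gene_selection `"double_filter"` (default) or `"all"` (skip DE
#'   and use every gene on the graph - useful when the signal of interest
#'   is covariance change without mean change).
#' @param p_threshold,fc_threshold Double-filter cutoffs (0.05, 1.5).
#' @param fc_mode Fold-change mode, see [differential_expression()].
#' @param bin_width Entropy group width in bits, default 3.
#' @param origin Entropy group anchor, default 0.
#' @param neighbor_scope Local-network neighbor lookup, `"full"` (default)
#'   or `"selected"`; see [all_local_networks()].
#' @param orientation_global,orientation_local Covariance orientations.
#' @param singularity,ridge Singular-covariance policy for local networks.
#' @param ddof Covariance denominator correction, default 1.
#' @return Object of class `netent_report`: list with `selected_genes`,
#'   `coverage`, `de` (the differential records, NULL when skipped),
#'   `profiles`, `trajectory`, `sudden_change` (per series), `groups`,
#'   `transitions` (one report per consecutive stage pair), `comparisons`
#'   (per non-control stage), `summaries`, and `params`.
#' @export
run_pipeline <- function(expr, manifest, graph,
                         id_map = NULL, keep_taxon = NULL,
                         gene_selection = c("double_filter", "all"),
                         p_threshold = 0.05, fc_threshold = 1.5,
                         fc_mode = "linear_means",
                         bin_width = 3, origin = 0,
                         neighbor_scope = "full",
                         orientation_global = "samples_as_variables",
                         orientation_local = "genes_as_variables",
                         singularity = "ridge", ridge = 1e-8, ddof = 1) {
  gene_selection <- match.arg(gene_selection)
  if (missing(expr) || is.null(expr)) stop("missing input: expression matrix")
  if (missing(manifest) || is.null(manifest)) stop("missing input: sample manifest")
  if (missing(graph) || is.null(graph)) stop("missing input: interactome edge list or graph")
  validate_expression_matrix(expr)
  if (!igraph::is_igraph(graph)) graph <- clean_graph(graph, keep_taxon = keep_taxon)

  de <- NULL
  if (gene_selection == "double_filter") {
    de <- differential_expression(expr, manifest,
                                  p_threshold = p_threshold,
                                  fc_threshold = fc_threshold,
                                  fc_mode = fc_mode)
    per_stage <- lapply(split(de, de$stage), double_filter,
                        p_threshold = p_threshold, fc_threshold = fc_threshold)
    genes <- select_study_genes(per_stage, mode = "union")
  } else {
    genes <- intersect(rownames(expr), igraph::V(graph)$name)
    if (length(genes) == 0L) stop("no expression gene matches a graph node")
  }

  mapping <- map_selected_genes(graph, genes, id_map = id_map)
  if (length(mapping$nodes) == 0L) {
    stop("no selected gene maps onto the interactome")
  }
  locals <- all_local_networks(graph, mapping$nodes,
                               neighbor_scope = neighbor_scope)

  profiles <- lapply(manifest$stage_order, function(st) {
    stage_entropy_profile(expr, manifest, st, genes, locals,
                          orientation_global = orientation_global,
                          orientation_local = orientation_local,
                          singularity = singularity, ridge = ridge,
                          ddof = ddof)
  })
  names(profiles) <- manifest$stage_order

  traj <- entropy_trajectory(profiles, manifest)
  sudden <- list(global = detect_sudden_change(traj, "global"),
                 network = detect_sudden_change(traj, "network"))

  control <- manifest$stage_order[1L]
  groups <- build_entropy_groups(profiles[[control]]$local,
                                 bin_width = bin_width, origin = origin)

  pairs <- Map(c, manifest$stage_order[-length(manifest$stage_order)],
               manifest$stage_order[-1L])
  transitions <- lapply(pairs, function(pr) {
    common <- intersect(names(profiles[[pr[1L]]]$local),
                        names(profiles[[pr[2L]]]$local))
    g2 <- build_entropy_groups(profiles[[control]]$local[common],
                               bin_width = bin_width, origin = origin)
    detect_transition_genes(g2, profiles[[pr[1L]]]$local[common],
                            profiles[[pr[2L]]]$local[common],
                            stage_pair = pr)
  })
  names(transitions) <- vapply(pairs, paste, "", collapse = " -> ")

  comparisons <- lapply(setdiff(manifest$stage_order, control), function(st) {
    wilcoxon_compare(profiles[[st]]$local, profiles[[control]]$local)
  })
  names(comparisons) <- setdiff(manifest$stage_order, control)

  summaries <- lapply(profiles, function(p) summarize_entropy(p$local))

  structure(list(selected_genes = genes,
                 coverage = mapping$coverage,
                 de = de,
                 local_networks = locals,
                 profiles = profiles,
                 trajectory = traj,
                 sudden_change = sudden,
                 groups = groups,
                 transitions = transitions,
                 comparisons = comparisons,
                 summaries = summaries,
                 params = list(gene_selection = gene_selection,
                               p_threshold = p_threshold,
                               fc_threshold = fc_threshold,
                               fc_mode = fc_mode,
                               bin_width = bin_width, origin = origin,
                               neighbor_scope = neighbor_scope,
                               orientation_global = orientation_global,
                               orientation_local = orientation_local,
                               singularity = singularity, ridge = ridge,
                               ddof = ddof)),
            class = "netent_report")
}

#' @export
print.netent_report <- function(x, ...) {
  cat("netent report:", length(x$selected_genes), "selected genes,",
      sprintf("coverage %.1f%%\n", 100 * x$coverage))
  print(x$trajectory)
  sc <- x$sudden_change$global
  cat(sprintf("largest global change: %s -> %s (%+.4f bits)\n",
              sc$from_stage, sc$to_stage, sc$delta))
  sc <- x$sudden_change$network
  cat(sprintf("largest network change: %s -> %s (%+.4f bits)\n",
              sc$from_stage, sc$to_stage, sc$delta))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Serializes a [run_pipeline()] report as `report.json` plus flat TSV
#' tables (`trajectory.tsv`, `local_entropy.tsv`, `transitions.tsv`,
#' `comparisons.tsv`). Output is deterministic - no timestamps - so two
#' runs on the same inputs are byte-identical.
#'
#' @param report A `netent_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "netent_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$trajectory, file.path(dir, "trajectory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  le <- do.call(rbind, lapply(report$profiles, function(p) {
    data.frame(stage = p$stage, node = names(p$local),
               h_local = unname(p$local), stringsAsFactors = FALSE)
  }))
  utils::write.table(le, file.path(dir, "local_entropy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- do.call(rbind, lapply(names(report$transitions), function(nm) {
    t <- report$transitions[[nm]]
    if (nrow(t) == 0L) return(NULL)
    cbind(data.frame(pair = nm, stringsAsFactors = FALSE), as.data.frame(t))
  }))
  if (is.null(tr)) {
    tr <- data.frame(pair = character(0), gene = character(0),
                     h_from = numeric(0), h_to = numeric(0),
                     bin_from = integer(0), bin_to = integer(0))
  }
  utils::write.table(tr, file.path(dir, "transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp <- do.call(rbind, lapply(names(report$comparisons), function(st) {
    c <- report$comparisons[[st]]
    data.frame(stage = st, W = c$statistic, p_value = c$p_value,
               n_stage = c$n_stage, n_control = c$n_control,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(cmp, file.path(dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    selected_genes = report$selected_genes,
    coverage = report$coverage,
    trajectory = report$trajectory,
    sudden_change = report$sudden_change,
    groups = list(bin_width = report$groups$bin_width,
                  origin = report$groups$origin,
                  bins = report$groups$bins,
                  node_to_bin = as.list(report$groups$node_to_bin)),
    transitions = lapply(report$transitions, as.data.frame),
    comparisons = report$comparisons,
    summaries = report$summaries,
    params = report$params)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
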