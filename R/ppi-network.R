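#' Read a protein-protein interaction edge list
#'
#' Supports two plain-text layouts: `"tsv"` with two or more columns
#' (`node_a`, `node_b`, optional `taxon` tag in the third column) and no
#' header, and `"sif"` (`source relation target1 [target2 ...]`,
#' whitespace-delimited). Record order is preserved; cleanup (taxon
#' filtering, deduplication) is a separate step, [clean_graph()].
#'
#' @param path Path to the edge-list file.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param delimiter Field separator for `"tsv"`, default tab.
#' @return A data.frame with columns `a`, `b`, `taxon` (NA when untagged),
#'   one row per interaction record.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), delimiter = "\t") {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  if (format == "tsv") {
    fields <- strsplit(lines, delimiter, fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      stop(sprintf("edge list line %d has fewer than 2 fields",
                   which(nf < 2L)[1L]))
    }
    recs <- data.frame(
      a = vapply(fields, `[[`, "", 1L),
      b = vapply(fields, `[[`, "", 2L),
      taxon = vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, ""),
      stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop(sprintf("SIF line %d needs 'source relation target...' (>= 3 fields)",
                   which(nf < 3L)[1L]))
    }
    recs <- do.call(rbind, lapply(fields, function(f) {
      data.frame(a = f[[1L]], b = f[-(1:2)], taxon = NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(recs) <- NULL
  recs
}

#' Clean an interaction edge list into a simple undirected graph
#'
#' Applies the interactome cleanup rules: drop records of foreign taxa
#' (when `keep_taxon` is given; untagged records are kept), drop self-loops,
#' and collapse duplicate edges in either orientation. Returns an undirected
#' simple [igraph::graph] whose `cleanup` graph attribute reports the number
#' of records removed by each rule.
#'
#' @param records Data.frame with columns `a`, `b` and optionally `taxon`
#'   (as from [read_edge_list()]), or a two-column character matrix.
#' @param keep_taxon Optional taxon tag (e.g. `"9606"`); tagged records with
#'   any other tag are removed.
#' @return An undirected simple `igraph` graph with a `cleanup` attribute
#'   listing `foreign_taxon`, `self_loops`, `duplicates` counts.
#' @export
clean_graph <- function(records, keep_taxon = NULL) {
  if (is.matrix(records)) {
    records <- data.frame(a = records[, 1L], b = records[, 2L],
                          taxon = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("a", "b") %in% names(records)))
  if (is.null(records$taxon)) records$taxon <- rep(NA_character_, nrow(records))
  n0 <- nrow(records)
  if (!is.null(keep_taxon)) {
    keep <- is.na(records$taxon) | records$taxon == as.character(keep_taxon)
    n_foreign <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  } else {
    n_foreign <- 0L
  }
  loops <- records$a == records$b
  n_loops <- sum(loops)
  records <- records[!loops, , drop = FALSE]
  key <- ifelse(records$a < records$b,
                paste(records$a, records$b, sep = "\r"),
                paste(records$b, records$a, sep = "\r"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(records$a, records$b), directed = FALSE)
  g <- igraph::set_graph_attr(g, "cleanup",
                              list(input_records = n0,
                                   foreign_taxon = n_foreign,
                                   self_loops = n_loops,
                                   duplicates = n_dup))
  g
}

#' Edge records of a graph
#'
#' Inverse of [clean_graph()] for round-trip checks and serialization.
#'
#' @param graph An `igraph` graph.
#' @return Data.frame with columns `a`, `b`, `taxon` (all NA).
#' @export
graph_records <- function(graph) {
  el <- igraph::as_edgelist(graph)
  data.frame(a = el[, 1L], b = el[, 2L], taxon = NA_character_,
             stringsAsFactors = FALSE)
}

#' Map selected genes onto the interactome
#'
#' Matches a selected gene set to graph nodes, optionally through a
#' user-supplied gene-to-protein identifier table, and reports the mapping
#' coverage. Coverage below 50% triggers a warning (not an error): sparse
#' interactome annotation routinely loses a sizeable fraction of selected
#' genes, and the analysis proceeds on the mapped subset.
#'
#' @param graph Cleaned `igraph` interactome.
#' @param genes Character vector of selected gene ids.
#' @param id_map Optional data.frame/matrix whose first two columns are
#'   `gene_id`, `protein_id`; identity mapping when omitted.
#' @return List with `nodes` (mapped node ids, in gene order) and
#'   `coverage` (fraction of `genes` that mapped).
#' @export
map_selected_genes <- function(graph, genes, id_map = NULL) {
  if (length(genes) == 0L) stop("empty gene set")
  genes <- unique(as.character(genes))
  if (!is.null(id_map)) {
    id_map <- as.data.frame(id_map, stringsAsFactors = FALSE)
    lookup <- stats::setNames(as.character(id_map[[2L]]), as.character(id_map[[1L]]))
    target <- lookup[genes]
  } else {
    target <- stats::setNames(genes, genes)
  }
  node_ids <- igraph::V(graph)$name
  mapped_gene <- !is.na(target) & target %in% node_ids
  nodes <- unique(unname(target[mapped_gene]))
  coverage <- sum(mapped_gene) / length(genes)
  if (coverage < 0.5) {
    warning(sprintf("only %.1f%% of selected genes mapped onto the interactome (< 50%%)",
                    100 * coverage))
  }
  list(nodes = nodes, coverage = coverage)
}

#' First-neighbor local network of a node
#'
#' A local network is a node together with all of its first (direct)
#' neighbors in the interactome; its size is `degree(node) + 1`.
#'
#' @param graph An `igraph` graph with named vertices.
#' @param node Node identifier.
#' @return Object of class `local_network`: list with `center` and
#'   `members` (center first, then sorted neighbors).
#' @export
local_network <- function(graph, node) {
  node <- as.character(node)
  if (!node %in% igraph::V(graph)$name) stop("node not in graph: ", node)
  nb <- igraph::neighbors(graph, node)$name
  structure(list(center = node, members = c(node, sort(unique(nb)))),
            class = "local_network")
}

#' @export
print.local_network <- function(x, ...) {
  cat("local network of", x$center, "-", length(x$members), "members\n")
  invisible(x)
}

#' Local networks of all mapped nodes
#'
#' One [local_network()] per mapped node, in sorted node-id order.
#' `neighbor_scope` controls where neighbors are looked up: the full
#' cleaned interactome (`"full"`, default - the local network of a selected
#' gene may contain unselected neighbors) or the subgraph induced by the
#' mapped nodes (`"selected"`).
#'
#' @param graph Cleaned `igraph` interactome.
#' @param nodes Mapped node ids (must be in the graph).
#' @param neighbor_scope `"full"` (default) or `"selected"`.
#' @return Named list of `local_network` objects, sorted by node id.
#' @export
all_local_networks <- function(graph, nodes,
                               neighbor_scope = c("full", "selected")) {
  neighbor_scope <- match.arg(neighbor_scope)
  nodes <- sort(unique(as.character(nodes)))
  missing <- setdiff(nodes, igraph::V(graph)$name)
  if (length(missing) > 0L) {
    stop("node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  g <- if (neighbor_scope == "selected") {
    igraph::induced_subgraph(graph, nodes)
  } else {
    graph
  }
  stats::setNames(lapply(nodes, function(v) local_network(g, v)), nodes)
}
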