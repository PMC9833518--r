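#' Build the annotation-overlap graph
#'
#' One node per gene set across all supplied datasets (grouped by a
#' `dataset` node attribute, not by layout), with an undirected edge
#' between any two sets — including sets from different datasets — whose
#' shared-gene proportion exceeds `min_weight`. The default proportion is
#' the Jaccard index |A∩B| / |A∪B|; the overlap coefficient
#' |A∩B| / min(|A|, |B|) is available behind `weight_method`. The graph
#' depends only on the datasets, so repeated calls are identical; query
#' significance is layered on afterwards with [overlay_query()].
#'
#' @param datasets List of `hyperora_dataset` objects.
#' @param min_weight Edges with weight `<= min_weight` are omitted;
#'   default 0.05 keeps dense collections readable.
#' @param weight_method `"jaccard"` (default) or `"overlap"`.
#' @return An undirected [igraph::igraph] graph with vertex attributes
#'   `name` (`"<dataset_id>::<set_id>"`), `dataset`, `set_id`, `size`,
#'   and edge attribute `weight`.
#' @export
build_graph <- function(datasets, min_weight = 0.05,
                        weight_method = c("jaccard", "overlap")) {
  weight_method <- match.arg(weight_method)
  if (inherits(datasets, "hyperora_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0) stop("no datasets supplied", call. = FALSE)
  stopifnot(all(vapply(datasets, inherits, logical(1), "hyperora_dataset")))
  if (min_weight < 0 || min_weight >= 1) {
    stop("min_weight must lie in [0, 1)", call. = FALSE)
  }

  members <- list()
  nodes <- list()
  for (ds in datasets) {
    for (s in ds$gene_sets) {
      id <- paste0(ds$dataset_id, "::", s$set_id)
      members[[id]] <- s$members$normalized_key
      nodes[[id]] <- data.frame(
        name = id, dataset = ds$dataset_id, set_id = s$set_id,
        size = length(s$members$normalized_key), stringsAsFactors = FALSE)
    }
  }
  vertices <- do.call(rbind, nodes)
  rownames(vertices) <- NULL

  ids <- vertices$name
  edges <- list()
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      a <- members[[ids[i]]]
      for (j in seq(i + 1, length(ids))) {
        b <- members[[ids[j]]]
        inter <- length(intersect(a, b))
        if (inter == 0) next
        w <- switch(weight_method,
                    jaccard = inter / length(union(a, b)),
                    overlap = inter / min(length(a), length(b)))
        if (w > min_weight) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = ids[i], to = ids[j], weight = w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = vertices)
  g$min_weight <- min_weight
  g$weight_method <- weight_method
  g
}

#' Overlay per-query significance on the annotation graph
#'
#' Sets the vertex attribute `score` to `-log10(p_enrich)` for every gene
#' set tested for the named query; untested nodes get `NA`. The topology
#' is untouched, so overlaying a second query fully replaces the first.
#'
#' @param graph Graph from [build_graph()].
#' @param results An `hyperora_results` data frame from [enrich()].
#' @param query_name Which query list to visualize.
#' @return The graph with updated `score` and a `query` graph attribute.
#' @export
overlay_query <- function(graph, results, query_name) {
  stopifnot(inherits(results, "hyperora_results"))
  available <- unique(results$query)
  if (!query_name %in% available) {
    stop("unknown query '", query_name, "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  sub <- results[results$query == query_name, , drop = FALSE]
  node_id <- paste0(sub$dataset_id, "::", sub$set_id)
  score <- stats::setNames(-log10(sub$p_enrich), node_id)
  v <- igraph::V(graph)$name
  igraph::V(graph)$score <- unname(score[v])
  graph$query <- query_name
  graph
}

#' Export the annotation graph
#'
#' Writes the graph, including dataset grouping, set sizes, any overlay
#' scores, and edge weights, as GraphML or Cytoscape-style JSON
#' (`elements` with `data.id` / `data.source` / `data.target`). Nodes and
#' edges are serialized in graph order, which [build_graph()] makes
#' deterministic.
#'
#' @param graph Graph from [build_graph()] / [overlay_query()].
#' @param format `"graphml"` or `"cytoscape_json"`.
#' @param sink Output file path.
#' @return Invisibly, `sink`.
#' @export
export_graph <- function(graph, format = c("graphml", "cytoscape_json"), sink) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, sink, format = "graphml")
    return(invisible(sink))
  }
  v <- igraph::as_data_frame(graph, what = "vertices")
  e <- igraph::as_data_frame(graph, what = "edges")
  node_el <- lapply(seq_len(nrow(v)), function(i) {
    d <- list(id = v$name[i], dataset = v$dataset[i], set_id = v$set_id[i],
              size = v$size[i])
    if (!is.null(v$score) && !is.na(v$score[i])) d$score <- v$score[i]
    list(data = d)
  })
  edge_el <- lapply(seq_len(nrow(e)), function(i) {
    list(data = list(id = paste0("e", i), source = e$from[i],
                     target = e$to[i], weight = e$weight[i]))
  })
  jsonlite::write_json(
    list(elements = list(nodes = node_el, edges = edge_el)),
    sink, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sink)
}
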