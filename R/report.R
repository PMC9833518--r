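#' Table of significantly enriched annotations
#'
#' Flattens enrichment results to the familiar significant-hits table:
#' source dataset, annotation, query list, raw and adjusted p-values, the
#' hypergeometric parameters, and the full overlap gene list
#' (semicolon-joined, sorted). Rows are filtered to raw p (or FDR when
#' `use_fdr`) at or below `cutoff`, and sorted ascending by p with
#' (dataset, annotation) lexicographic tie-breaks.
#'
#' @param results An `hyperora_results` data frame from [enrich()].
#' @param cutoff Inclusive significance cutoff (default 0.05).
#' @param use_fdr Filter on the BH-adjusted value instead of raw p.
#' @param file Optional path; when given the table is also written as CSV.
#' @return A data frame with columns `dataset`, `annotation`, `query`,
#'   `p_value`, `fdr`, `N`, `n`, `K`, `k`, `overlap_genes`. When no row
#'   passes the cutoff a header-only table is returned with a message.
#' @export
results_table <- function(results, cutoff = 0.05, use_fdr = FALSE,
                          file = NULL) {
  stopifnot(inherits(results, "hyperora_results"), nrow(results) > 0)
  stat <- if (use_fdr) results$fdr else results$p_enrich
  keep <- stat <= cutoff
  tab <- data.frame(
    dataset = results$dataset_id,
    annotation = results$set_id,
    query = results$query,
    p_value = results$p_enrich,
    fdr = results$fdr,
    N = results$N, n = results$n, K = results$K, k = results$k,
    overlap_genes = vapply(results$overlap_genes,
                           function(g) paste(sort(g), collapse = ";"),
                           character(1)),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  tab <- tab[order(tab$p_value, tab$dataset, tab$annotation, tab$query), ,
             drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) == 0) {
    message("no annotations pass the ", if (use_fdr) "FDR" else "p-value",
            " cutoff of ", cutoff)
  }
  if (!is.null(file)) {
    write.csv(tab, file, row.names = FALSE)
  }
  tab
}

#' Classify results into a query-by-annotation heatmap matrix
#'
#' Rows are query lists, columns are annotations in dataset gene-set
#' order. A cell is `enriched` when its p-value is at or below
#' `enrich_cutoff`, `depleted` when at or above `deplete_cutoff` (the
#' defaults 0.05 / 0.95 match the usual two-sided reading of the upper
#' tail), otherwise `neither`; untested pairs are `NA`. Each cell also
#' carries a signed gradient score: `-log10(p)` on the enrichment side
#' (`p < 0.5`, positive) and `log10(1 - p)` on the depletion side
#' (negative), clamped to +/-300 so deterministic overlaps stay finite.
#'
#' @param results An `hyperora_results` data frame.
#' @param enrich_cutoff,deplete_cutoff Probability cutoffs with
#'   `enrich_cutoff < deplete_cutoff`.
#' @param use_fdr Classify on BH-adjusted values instead of raw p.
#' @return An object of class `hyperora_heatmap`: list with `score` and
#'   `class` matrices (queries x annotations), `columns` (data frame of
#'   dataset / set per column) and the cutoffs.
#' @export
heatmap_matrix <- function(results, enrich_cutoff = 0.05,
                           deplete_cutoff = 0.95, use_fdr = FALSE) {
  stopifnot(inherits(results, "hyperora_results"))
  if (!(enrich_cutoff < deplete_cutoff)) {
    stop("enrich_cutoff must be smaller than deplete_cutoff", call. = FALSE)
  }
  col_id <- paste0(results$dataset_id, "::", results$set_id)
  cols <- unique(data.frame(id = col_id, dataset = results$dataset_id,
                            set = results$set_id, stringsAsFactors = FALSE))
  queries <- unique(results$query)
  score <- matrix(NA_real_, nrow = length(queries), ncol = nrow(cols),
                  dimnames = list(queries, cols$id))
  cls <- matrix(NA_character_, nrow = length(queries), ncol = nrow(cols),
                dimnames = list(queries, cols$id))
  p <- if (use_fdr) results$fdr else results$p_enrich
  signed <- ifelse(p < 0.5,
                   pmin(-log10(pmax(p, 1e-300)), 300),
                   pmax(log10(pmax(1 - p, 1e-300)), -300))
  for (i in seq_len(nrow(results))) {
    score[results$query[i], col_id[i]] <- signed[i]
    cls[results$query[i], col_id[i]] <-
      if (p[i] <= enrich_cutoff) "enriched"
      else if (p[i] >= deplete_cutoff) "depleted"
      else "neither"
  }
  structure(
    list(score = score, class = cls, columns = cols,
         enrich_cutoff = enrich_cutoff, deplete_cutoff = deplete_cutoff,
         use_fdr = use_fdr),
    class = "hyperora_heatmap"
  )
}

#' Render a heatmap to PNG
#'
#' `"binary"` style paints enriched cells red, depleted cells blue and the
#' rest grey (untested cells white); `"gradient"` maps the signed
#' `-log10 p` score onto a symmetric blue-white-red diverging scale, so an
#' all-`neither` matrix renders near the white midpoint. With
#' `split_by_dataset` one file per dataset is written
#' (`<stem>_<dataset>.png`).
#'
#' @param matrix An `hyperora_heatmap` from [heatmap_matrix()].
#' @param style `"binary"` or `"gradient"`.
#' @param file Output PNG path.
#' @param split_by_dataset Write one image per dataset.
#' @param width,height Device size in pixels.
#' @return Invisibly, the path(s) written.
#' @export
render_heatmap <- function(matrix, style = c("binary", "gradient"), file,
                           split_by_dataset = FALSE, width = 900,
                           height = 400) {
  style <- match.arg(style)
  stopifnot(inherits(matrix, "hyperora_heatmap"))
  if (split_by_dataset) {
    stem <- sub("\\.png$", "", file)
    paths <- character()
    for (ds in unique(matrix$columns$dataset)) {
      keep <- matrix$columns$dataset == ds
      sub <- matrix
      sub$score <- matrix$score[, keep, drop = FALSE]
      sub$class <- matrix$class[, keep, drop = FALSE]
      sub$columns <- matrix$columns[keep, , drop = FALSE]
      path <- paste0(stem, "_", ds, ".png")
      render_heatmap(sub, style, path, split_by_dataset = FALSE,
                     width = width, height = height)
      paths <- c(paths, path)
    }
    return(invisible(paths))
  }

  grDevices::png(file, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(8, 8, 3, 6))
  on.exit(graphics::par(op), add = TRUE)

  nr <- nrow(matrix$score)
  nc <- ncol(matrix$score)
  if (style == "binary") {
    code <- matrix(0, nr, nc)  # 0 untested, 1 neither, 2 depleted, 3 enriched
    code[matrix$class == "neither"] <- 1
    code[matrix$class == "depleted"] <- 2
    code[matrix$class == "enriched"] <- 3
    pal <- c("white", "grey85", "#2166AC", "#B2182B")
    z <- t(code)[, rev(seq_len(nr)), drop = FALSE]
    graphics::image(seq_len(nc), seq_len(nr), z,
                    col = pal, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5),
                    axes = FALSE, xlab = "", ylab = "",
                    main = sprintf("enriched p <= %g / depleted p >= %g",
                                   matrix$enrich_cutoff, matrix$deplete_cutoff))
  } else {
    lim <- max(abs(matrix$score), 1, na.rm = TRUE)
    pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
    z <- t(matrix$score)[, rev(seq_len(nr)), drop = FALSE]
    graphics::image(seq_len(nc), seq_len(nr), z,
                    col = pal, zlim = c(-lim, lim),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "signed -log10 p (red enriched, blue depleted)")
  }
  graphics::axis(1, at = seq_len(nc), labels = colnames(matrix$score),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(matrix$score)),
                 las = 2, cex.axis = 0.8, tick = FALSE)
  graphics::box()
  invisible(file)
}

#' Report genes that do not cross between inputs and datasets
#'
#' Three sections mirror the usual end-of-run diagnostics: query genes
#' found in no dataset universe (typos or out-of-domain genes, listed with
#' their source list), background genes found in no universe, and dataset
#' universe genes absent from the background. Each section is sorted and
#' counted.
#'
#' @param collection An `hyperora_collection`.
#' @param datasets List of `hyperora_dataset` objects.
#' @return An object of class `hyperora_unmatched`: list with
#'   `query_unmatched` (data frame `gene`, `list_name`),
#'   `background_unmatched` and `dataset_unmatched` (character vectors).
#' @export
unmatched_report <- function(collection, datasets) {
  stopifnot(inherits(collection, "hyperora_collection"))
  if (inherits(datasets, "hyperora_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) > 0,
            all(vapply(datasets, inherits, logical(1), "hyperora_dataset")))
  all_universe <- sort(unique(unlist(lapply(datasets, function(d) d$universe),
                                     use.names = FALSE)))
  qrows <- list()
  for (nm in names(collection$queries)) {
    q <- collection$queries[[nm]]
    out <- !q$normalized_key %in% all_universe
    if (any(out)) {
      qrows[[nm]] <- data.frame(gene = sort(q$raw_label[out]), list_name = nm,
                                stringsAsFactors = FALSE)
    }
  }
  query_unmatched <- if (length(qrows)) do.call(rbind, qrows) else
    data.frame(gene = character(), list_name = character(),
               stringsAsFactors = FALSE)
  rownames(query_unmatched) <- NULL
  bg <- collection$background
  background_unmatched <- sort(bg$raw_label[!bg$normalized_key %in% all_universe])
  dataset_unmatched <- sort(setdiff(all_universe, bg$normalized_key))
  structure(
    list(query_unmatched = query_unmatched,
         background_unmatched = background_unmatched,
         dataset_unmatched = dataset_unmatched),
    class = "hyperora_unmatched"
  )
}

#' @export
format.hyperora_unmatched <- function(x, ...) {
  fmt_sec <- function(title, items) {
    c(sprintf("## %s (%d)", title, length(items)),
      if (length(items)) items else "(none)", "")
  }
  c(fmt_sec("Query genes in no dataset universe",
            if (nrow(x$query_unmatched)) {
              sprintf("%s\t(list: %s)", x$query_unmatched$gene,
                      x$query_unmatched$list_name)
            } else character()),
    fmt_sec("Background genes in no dataset universe", x$background_unmatched),
    fmt_sec("Dataset genes absent from the background", x$dataset_unmatched))
}

#' @export
print.hyperora_unmatched <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
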