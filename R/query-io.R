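#' Parse a single query gene list
#'
#' Reads one gene label per line, ignoring blank lines, and returns a
#' single named, normalized, de-duplicated gene set. Duplicate labels
#' (after normalization, so `Fcgr1` and `FCGR1` collide) are dropped with
#' a warning reporting the count.
#'
#' @param source File path or connection, one gene per line.
#' @param list_name Name for the query list.
#' @return A named list of length one mapping `list_name` to a normalized
#'   gene table.
#' @export
parse_single_query <- function(source, list_name = "query") {
  lines <- trimws(readLines(source, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop("query list '", list_name, "' is empty", call. = FALSE)
  }
  tab <- as_gene_table(lines)
  ndup <- sum(duplicated(tab$normalized_key))
  if (ndup > 0) {
    warning("query list '", list_name, "': removed ", ndup,
            " duplicate gene(s)", call. = FALSE)
  }
  out <- list(dedup_genes(tab))
  names(out) <- list_name
  out
}

#' Parse a multiple-query two-column CSV
#'
#' Each row is `gene,list`: the first field is a gene label and the second
#' assigns it to a named query list (for example a cluster label). Lists
#' are returned in first-appearance order; a gene may belong to several
#' lists, and within-list duplicates are removed with a warning. A first
#' row whose first field is (case-insensitively) `gene` or `genes` is
#' treated as a header.
#'
#' @param source File path or connection.
#' @return A named list mapping each list name to a normalized gene table.
#' @export
parse_multi_query <- function(source) {
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("query file is empty", call. = FALSE)
  fields <- strsplit(lines[keep], ",", fixed = TRUE)
  bad <- lengths(fields) != 2
  if (any(bad)) {
    i <- which(bad)[1]
    stop("multi-query format error: row ", keep[i], " ('",
         lines[keep[i]], "') does not have exactly 2 comma-separated fields",
         call. = FALSE)
  }
  gene_col <- trimws(vapply(fields, `[[`, character(1), 1))
  list_col <- trimws(vapply(fields, `[[`, character(1), 2))
  if (tolower(gene_col[1]) %in% c("gene", "genes")) {
    gene_col <- gene_col[-1]
    list_col <- list_col[-1]
  }
  if (length(gene_col) == 0) stop("query file has no data rows", call. = FALSE)
  queries <- list()
  for (nm in unique(list_col)) {
    tab <- as_gene_table(gene_col[list_col == nm])
    ndup <- sum(duplicated(tab$normalized_key))
    if (ndup > 0) {
      warning("query list '", nm, "': removed ", ndup,
              " duplicate gene(s)", call. = FALSE)
    }
    queries[[nm]] <- dedup_genes(tab)
  }
  queries
}

#' Assemble a validated query collection
#'
#' Combines parsed query lists with the user-supplied background into the
#' object consumed by [enrich()]. The hypergeometric model treats the
#' query as a draw from the background, so every query must be a subset of
#' it: by default, query genes absent from the background are dropped and
#' recorded per list; with `strict = TRUE` any such gene is an error.
#'
#' @param queries Named list of gene tables from [parse_single_query()] or
#'   [parse_multi_query()] (raw character vectors are also accepted).
#' @param background_source File path / connection with one background
#'   gene per line, or a character vector of labels.
#' @param strict If `TRUE`, query genes outside the background are an
#'   error instead of being dropped.
#' @return An object of class `hyperora_collection` with elements
#'   `queries` (named list of normalized tables), `background` (normalized
#'   table), and `dropped_from_queries` (named list of raw labels dropped
#'   per query).
#' @export
assemble_collection <- function(queries, background_source, strict = FALSE) {
  if (length(queries) == 0) stop("no query lists supplied", call. = FALSE)
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("every query list must be named", call. = FALSE)
  }
  if (anyDuplicated(names(queries))) {
    stop("duplicate query list name(s): ",
         paste(unique(names(queries)[duplicated(names(queries))]), collapse = ", "),
         call. = FALSE)
  }
  queries <- lapply(queries, function(q) dedup_genes(as_gene_table(q)))
  bg_labels <- if (is.character(background_source) &&
                   (length(background_source) > 1 ||
                    !file.exists(background_source))) {
    background_source
  } else {
    readLines(background_source, warn = FALSE, encoding = "UTF-8")
  }
  bg_labels <- trimws(bg_labels)
  bg_labels <- bg_labels[nzchar(bg_labels)]
  if (length(bg_labels) == 0) stop("background gene list is empty", call. = FALSE)
  background <- dedup_genes(as_gene_table(bg_labels))

  dropped <- list()
  for (nm in names(queries)) {
    inside <- queries[[nm]]$normalized_key %in% background$normalized_key
    if (!all(inside)) {
      offending <- queries[[nm]]$raw_label[!inside]
      if (strict) {
        stop("query list '", nm, "' contains ", length(offending),
             " gene(s) absent from the background: ",
             paste(head(offending, 10), collapse = ", "), call. = FALSE)
      }
      dropped[[nm]] <- offending
      queries[[nm]] <- queries[[nm]][inside, , drop = FALSE]
    } else {
      dropped[[nm]] <- character()
    }
    if (nrow(queries[[nm]]) == 0) {
      stop("query list '", nm,
           "' is empty after removing genes absent from the background",
           call. = FALSE)
    }
  }
  structure(
    list(queries = queries, background = background,
         dropped_from_queries = dropped),
    class = "hyperora_collection"
  )
}

#' @export
print.hyperora_collection <- function(x, ...) {
  cat("<query collection>\n")
  cat("  background:", nrow(x$background), "genes\n")
  for (nm in names(x$queries)) {
    nd <- length(x$dropped_from_queries[[nm]])
    cat(sprintf("  query '%s': %d genes%s\n", nm, nrow(x$queries[[nm]]),
                if (nd > 0) sprintf(" (%d dropped)", nd) else ""))
  }
  invisible(x)
}
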