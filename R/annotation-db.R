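#' Construct a gene-set annotation
#'
#' A gene set is a named collection of genes within a dataset, e.g. one
#' expression cluster from a published study. Members are normalized with
#' [normalize_gene_id()] and de-duplicated by normalized key.
#'
#' @param set_id Identifier, unique within its dataset.
#' @param members Character vector of gene labels (or a table from
#'   [normalize_gene_id()]).
#' @param display_name Human-readable name; defaults to `set_id`.
#' @param description Free-form description.
#' @return An object of class `hyperora_gene_set`.
#' @export
gene_set <- function(set_id, members, display_name = set_id, description = "") {
  stopifnot(is.character(set_id), length(set_id) == 1, nzchar(set_id))
  tab <- dedup_genes(as_gene_table(members))
  if (nrow(tab) == 0) {
    stop("gene set '", set_id, "' has no members", call. = FALSE)
  }
  structure(
    list(set_id = set_id, display_name = display_name,
         description = description, members = tab),
    class = "hyperora_gene_set"
  )
}

#' Construct an annotation dataset
#'
#' A dataset groups the gene sets curated from one source (one publication
#' or one custom upload) together with that source's gene universe — the
#' "total genes in the dataset" used when resolving the background in
#' INTERSECT mode. If no universe is given it defaults to the union of all
#' gene-set members; an explicit universe may be larger (a study's
#' expressed-gene background can exceed the union of its reported sets)
#' but must contain every member.
#'
#' @param dataset_id Identifier for the dataset.
#' @param gene_sets List of [gene_set()] objects, order preserved.
#' @param universe Optional character vector (or normalized table) of
#'   universe gene labels; default is the union of the members.
#' @param title,citation Free-form metadata.
#' @return An object of class `hyperora_dataset`.
#' @export
annotation_dataset <- function(dataset_id, gene_sets, universe = NULL,
                               title = dataset_id, citation = "") {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1, nzchar(dataset_id))
  if (length(gene_sets) == 0) {
    stop("dataset '", dataset_id, "' has no gene sets", call. = FALSE)
  }
  stopifnot(all(vapply(gene_sets, inherits, logical(1), "hyperora_gene_set")))
  ids <- vapply(gene_sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate gene set id(s) in dataset '", dataset_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(gene_sets) <- ids
  member_keys <- unique(unlist(lapply(gene_sets, function(s) s$members$normalized_key),
                               use.names = FALSE))
  if (is.null(universe)) {
    universe_keys <- sort(member_keys)
  } else {
    universe_keys <- sort(unique(as_gene_table(universe)$normalized_key))
    missing <- setdiff(member_keys, universe_keys)
    if (length(missing) > 0) {
      stop("dataset '", dataset_id, "': ", length(missing),
           " gene-set member(s) are absent from the supplied universe (e.g. ",
           paste(head(missing, 5), collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(
    list(dataset_id = dataset_id, title = title, citation = citation,
         gene_sets = gene_sets, universe = universe_keys),
    class = "hyperora_dataset"
  )
}

#' @export
print.hyperora_dataset <- function(x, ...) {
  cat("<annotation dataset> ", x$dataset_id, "\n", sep = "")
  if (nzchar(x$title) && !identical(x$title, x$dataset_id)) {
    cat("  title:    ", x$title, "\n", sep = "")
  }
  cat("  gene sets:", length(x$gene_sets), "\n")
  cat("  universe: ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read an annotation dataset from a GMT file
#'
#' GMT is the tab-separated gene-set interchange format: one set per line
#' as `name<TAB>description<TAB>gene1<TAB>gene2...`. Members are
#' normalized and de-duplicated per set; line order is preserved. Blank
#' lines are skipped with a warning.
#'
#' @param source File path or connection.
#' @param dataset_id Identifier for the resulting dataset; defaults to the
#'   source file name without extension.
#' @param universe_override Optional gene labels for the dataset universe
#'   (e.g. the study's full expressed-gene list); default is the union of
#'   all set members.
#' @param title,citation Free-form metadata.
#' @return An object of class `hyperora_dataset`.
#' @export
read_gmt <- function(source, dataset_id = NULL, universe_override = NULL,
                     title = NULL, citation = "") {
  if (is.null(dataset_id)) {
    dataset_id <- if (is.character(source)) {
      sub("\\.[^.]*$", "", basename(source))
    } else "dataset"
  }
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning("skipping ", sum(blank), " blank line(s) in GMT for '",
            dataset_id, "'", call. = FALSE)
  }
  keep <- which(!blank)
  if (length(keep) == 0) {
    stop("GMT source for '", dataset_id, "' contains no gene sets", call. = FALSE)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop("GMT format error: line ", keep[which(short)[1]],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  set_names <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(set_names)) {
    stop("GMT format error: duplicate set name(s): ",
         paste(unique(set_names[duplicated(set_names)]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    gene_set(set_id = f[[1]], display_name = f[[1]], description = f[[2]],
             members = f[-(1:2)])
  })
  annotation_dataset(dataset_id, sets, universe = universe_override,
                     title = if (is.null(title)) dataset_id else title,
                     citation = citation)
}

#' Write an annotation dataset to a GMT file
#'
#' One line per gene set in dataset order; members are written as their
#' raw labels, sorted by normalized key so output is deterministic.
#'
#' @param dataset An `hyperora_dataset`.
#' @param sink File path or writable connection.
#' @return Invisibly, the sink.
#' @export
write_gmt <- function(dataset, sink) {
  stopifnot(inherits(dataset, "hyperora_dataset"))
  if (length(dataset$gene_sets) == 0) {
    stop("cannot write a dataset with no gene sets to GMT", call. = FALSE)
  }
  lines <- vapply(dataset$gene_sets, function(s) {
    m <- s$members[order(s$members$normalized_key), , drop = FALSE]
    paste(c(s$set_id, s$description, m$raw_label), collapse = "\t")
  }, character(1))
  writeLines(lines, sink, useBytes = TRUE)
  invisible(sink)
}

#' Look up gene-set memberships for individual genes
#'
#' Returns one record per (gene, gene set) membership across all supplied
#' datasets, ordered by dataset then set — the batch equivalent of an
#' individual-gene query interface. Genes with no memberships anywhere are
#' reported separately as unmatched.
#'
#' @param genes Character vector of gene labels (or normalized table).
#' @param datasets List of `hyperora_dataset` objects.
#' @return A list with `records` (data frame: `gene`, `normalized_key`,
#'   `dataset_id`, `set_id`, `set_display_name`) and `unmatched`
#'   (character vector of raw labels with no memberships).
#' @export
lookup_genes <- function(genes, datasets) {
  if (length(datasets) == 0) stop("no datasets supplied", call. = FALSE)
  stopifnot(all(vapply(datasets, inherits, logical(1), "hyperora_dataset")))
  tab <- dedup_genes(as_gene_table(genes))
  rows <- list()
  for (ds in datasets) {
    for (s in ds$gene_sets) {
      hit <- tab$normalized_key %in% s$members$normalized_key
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = tab$raw_label[hit],
          normalized_key = tab$normalized_key[hit],
          dataset_id = ds$dataset_id,
          set_id = s$set_id,
          set_display_name = s$display_name,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), normalized_key = character(),
               dataset_id = character(), set_id = character(),
               set_display_name = character(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  matched <- unique(records$normalized_key)
  list(records = records,
       unmatched = tab$raw_label[!tab$normalized_key %in% matched])
}
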