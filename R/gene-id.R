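#' Normalize gene identifiers
#'
#' Gene labels arrive from heterogeneous sources (user lists, GMT files)
#' as either MGI-style symbols or Ensembl mouse gene IDs. Matching across
#' sources is done on a normalized key: symbols are matched
#' case-insensitively (the key is the upper-cased, trimmed label) and
#' Ensembl IDs additionally have any `.<digits>` version suffix removed.
#' No cross-mapping between symbols and Ensembl IDs is attempted; two
#' identifiers are the same gene if and only if their keys are equal.
#'
#' @param raw Character vector of gene labels as supplied.
#' @return A data frame with one row per input label and columns
#'   `raw_label`, `normalized_key`, and `id_kind` (`"symbol"` or
#'   `"ensembl"`).
#' @examples
#' normalize_gene_id(c("Fcgr1", "ENSMUSG00000015947.12", "  Car4 "))
#' @export
normalize_gene_id <- function(raw) {
  if (length(raw) == 0) {
    return(data.frame(raw_label = character(), normalized_key = character(),
                      id_kind = character(), stringsAsFactors = FALSE))
  }
  if (!is.character(raw)) {
    stop("gene identifiers must be supplied as character labels", call. = FALSE)
  }
  trimmed <- trimws(raw)
  bad <- is.na(trimmed) | trimmed == ""
  if (any(bad)) {
    stop("invalid gene identifier(s): ",
         paste(sprintf("'%s'", raw[bad]), collapse = ", "),
         " (empty after trimming)", call. = FALSE)
  }
  ws <- grepl("[[:space:]]", trimmed)
  if (any(ws)) {
    stop("invalid gene identifier(s): ",
         paste(sprintf("'%s'", raw[ws]), collapse = ", "),
         " (internal whitespace)", call. = FALSE)
  }
  key <- toupper(trimmed)
  # strip Ensembl version suffix (ENSMUSG00000015947.12 -> ENSMUSG00000015947)
  key <- sub("^(ENSMUSG[0-9]+)\\.[0-9]+$", "\\1", key)
  kind <- ifelse(grepl("^ENSMUSG[0-9]+$", key), "ensembl", "symbol")
  data.frame(raw_label = trimmed, normalized_key = key, id_kind = kind,
             stringsAsFactors = FALSE)
}

# De-duplicate a normalized gene table by key, keeping the first raw label.
dedup_genes <- function(genes) {
  genes[!duplicated(genes$normalized_key), , drop = FALSE]
}

# Coerce raw labels / a normalize_gene_id() table to a normalized table.
as_gene_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("raw_label", "normalized_key", "id_kind") %in% names(x)))
    x
  } else {
    normalize_gene_id(x)
  }
}
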