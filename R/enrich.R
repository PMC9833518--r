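#' Hypergeometric upper-tail probability
#'
#' The probability of observing an overlap of `k` or more genes by chance
#' when a query of `n` genes is drawn without replacement from a
#' background of `N` genes of which `K` carry the annotation:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)}
#'   \frac{\binom{n}{i}\binom{N-n}{K-i}}{\binom{N}{K}}}
#' Evaluated through the hypergeometric survival function
#' (`stats::phyper`), which works in log space and is numerically stable
#' for large parameters; agreement with exact rational arithmetic is part
#' of the test suite.
#'
#' @param N Background size. @param n Query size.
#' @param K Annotated genes in the background.
#' @param k Annotated genes in the query.
#' @return `P(X >= k)`, in `(0, 1]`. Vectorized over its arguments.
#' @examples
#' hypergeom_upper_tail(N = 10, n = 5, K = 4, k = 3) # 11/42
#' @export
hypergeom_upper_tail <- function(N, n, K, k) {
  check_hg_params(N, n, K, k)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

check_hg_params <- function(N, n, K, k) {
  v <- c(N, n, K, k)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
    stop("hypergeometric parameters must be non-negative integers", call. = FALSE)
  }
  if (any(n > N)) stop("hypergeometric parameter violation: n > N", call. = FALSE)
  if (any(K > N)) stop("hypergeometric parameter violation: K > N", call. = FALSE)
  if (any(k > pmin(n, K))) {
    stop("hypergeometric parameter violation: k > min(n, K)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Resolve the effective background and query for one dataset
#'
#' Two settings control the background size `N` entering the test:
#' * `"intersect"` (default): the background is intersected with the
#'   dataset's gene universe, and the query is restricted the same way, so
#'   the test is conditioned on genes the dataset could have annotated.
#' * `"user"`: the supplied background and query are used unchanged —
#'   preferable when the overlap between the user's background and the
#'   dataset universe is limited.
#'
#' @param query,background Character vectors of normalized gene keys with
#'   `query` a subset of `background`.
#' @param dataset An `hyperora_dataset`.
#' @param mode `"intersect"` or `"user"`.
#' @return A list with `background` and `query` (normalized-key vectors),
#'   plus `degenerate` (logical) and `reason`: under `"intersect"` an
#'   empty effective background or query makes the dataset untestable, a
#'   condition reported to the caller rather than an error.
#' @export
resolve_background <- function(query, background, dataset,
                               mode = c("intersect", "user")) {
  mode <- match.arg(tolower(mode), c("intersect", "user"))
  stopifnot(inherits(dataset, "hyperora_dataset"))
  if (!all(query %in% background)) {
    stop("query is not a subset of the background", call. = FALSE)
  }
  if (mode == "user") {
    return(list(background = background, query = query,
                degenerate = FALSE, reason = NA_character_))
  }
  eff_bg <- intersect(background, dataset$universe)
  eff_q <- intersect(query, dataset$universe)
  degenerate <- length(eff_bg) == 0 || length(eff_q) == 0
  reason <- if (length(eff_bg) == 0) {
    "background has no genes in the dataset universe"
  } else if (length(eff_q) == 0) {
    "query has no genes in the dataset universe"
  } else NA_character_
  list(background = eff_bg, query = eff_q,
       degenerate = degenerate, reason = reason)
}

#' Test one query against one gene set
#'
#' Counts the overlaps that parameterize the hypergeometric test:
#' `K` annotated genes in the effective background, `k` annotated genes in
#' the query, with `N` and `n` the set sizes. A gene set with `K = 0`
#' cannot be tested and is signalled by a `NULL` return (the caller skips
#' and reports it).
#'
#' @param query,effective_background Normalized-key vectors, `query` a
#'   subset of `effective_background`.
#' @param gene_set An `hyperora_gene_set`.
#' @return `NULL` if `K = 0`; otherwise a list with `N`, `n`, `K`, `k`,
#'   `overlap` (sorted keys) and `p_enrich`.
#' @export
test_one <- function(query, effective_background, gene_set) {
  stopifnot(inherits(gene_set, "hyperora_gene_set"))
  if (!all(query %in% effective_background)) {
    stop("query is not a subset of the effective background", call. = FALSE)
  }
  members <- gene_set$members$normalized_key
  K <- sum(members %in% effective_background)
  if (K == 0) return(NULL)
  overlap <- sort(intersect(query, members))
  k <- length(overlap)
  N <- length(effective_background)
  n <- length(query)
  list(N = N, n = n, K = K, k = k, overlap = overlap,
       p_enrich = hypergeom_upper_tail(N, n, K, k))
}

#' Benjamini-Hochberg adjustment over a declared comparison count
#'
#' Step-up BH-FDR where the rank divisor runs out of `m`, the total number
#' of comparisons performed — for a multi-query run, the number of query
#' lists times the number of annotations tested across all datasets — so
#' adjustment is global rather than per dataset.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param m Total comparison count, at least `length(pvalues)`.
#' @return Adjusted values in input order, capped at 1.
#' @export
bh_adjust <- function(pvalues, m = length(pvalues)) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(pvalues)) {
    stop("m must be at least the number of p-values", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH", n = m)
}

#' Run the full enrichment analysis
#'
#' Performs one hypergeometric upper-tail test for every (query list,
#' gene set) pair across all datasets, with the background resolved per
#' dataset by `mode`. Depletion is scored as the complementary
#' probability `1 - p_enrich` exactly. BH-FDR is applied once, jointly
#' across every performed test (`m` = number of rows), not per dataset.
#'
#' @param collection An `hyperora_collection` from [assemble_collection()].
#' @param datasets List of `hyperora_dataset` objects.
#' @param mode Background mode, `"intersect"` (default) or `"user"`.
#' @return A data frame of class `hyperora_results`, one row per
#'   performed test in (dataset, gene set, query) order, with columns
#'   `dataset_id`, `set_id`, `query`, `N`, `n`, `K`, `k`, `p_enrich`,
#'   `p_deplete`, `fdr`, and list-column `overlap_genes`. Attributes:
#'   `m` (comparison count used for FDR) and `skipped` (data frame of
#'   untested pairs with reasons).
#' @export
enrich <- function(collection, datasets, mode = c("intersect", "user")) {
  mode <- match.arg(tolower(mode), c("intersect", "user"))
  stopifnot(inherits(collection, "hyperora_collection"))
  if (inherits(datasets, "hyperora_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0) stop("no datasets supplied", call. = FALSE)
  stopifnot(all(vapply(datasets, inherits, logical(1), "hyperora_dataset")))
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate dataset id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  background <- collection$background$normalized_key

  # accumulate per-row lists; one data frame is built at the end so large
  # sweeps (thousands of query x set pairs) stay cheap
  rows <- vector("list", 1024L)
  nrows <- 0L
  skipped <- list()
  note_skip <- function(dataset_id, set_id, query, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      dataset_id = dataset_id, set_id = set_id, query = query,
      reason = reason, stringsAsFactors = FALSE)
  }

  for (ds in datasets) {
    resolved <- list()
    for (qname in names(collection$queries)) {
      q <- collection$queries[[qname]]$normalized_key
      res <- resolve_background(q, background, ds, mode)
      if (res$degenerate) {
        note_skip(ds$dataset_id, NA_character_, qname, res$reason)
      } else {
        resolved[[qname]] <- res
      }
    }
    for (s in ds$gene_sets) {
      for (qname in names(resolved)) {
        res <- resolved[[qname]]
        t1 <- test_one(res$query, res$background, s)
        if (is.null(t1)) {
          note_skip(ds$dataset_id, s$set_id, qname,
                    "no annotated genes in the effective background (K = 0)")
          next
        }
        nrows <- nrows + 1L
        if (nrows > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nrows]] <- list(dataset_id = ds$dataset_id, set_id = s$set_id,
                              query = qname, t1 = t1)
      }
    }
  }
  rows <- rows[seq_len(nrows)]

  if (nrows == 0L) {
    stop("no testable (query, gene set) pairs; under 'intersect' mode ",
         "this can happen when the background barely overlaps the dataset ",
         "universes - consider mode = 'user'", call. = FALSE)
  }
  out <- data.frame(
    dataset_id = vapply(rows, `[[`, character(1), "dataset_id"),
    set_id = vapply(rows, `[[`, character(1), "set_id"),
    query = vapply(rows, `[[`, character(1), "query"),
    N = vapply(rows, function(r) r$t1$N, integer(1)),
    n = vapply(rows, function(r) r$t1$n, integer(1)),
    K = vapply(rows, function(r) r$t1$K, integer(1)),
    k = vapply(rows, function(r) r$t1$k, integer(1)),
    p_enrich = vapply(rows, function(r) r$t1$p_enrich, numeric(1)),
    stringsAsFactors = FALSE)
  out$overlap_genes <- lapply(rows, function(r) r$t1$overlap)
  out$p_deplete <- 1 - out$p_enrich
  m <- nrow(out)
  out$fdr <- bh_adjust(out$p_enrich, m = m)
  out <- out[, c("dataset_id", "set_id", "query", "N", "n", "K", "k",
                 "p_enrich", "p_deplete", "fdr", "overlap_genes")]
  attr(out, "m") <- m
  attr(out, "mode") <- mode
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(dataset_id = character(), set_id = character(),
               query = character(), reason = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("hyperora_results", class(out))
  out
}
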