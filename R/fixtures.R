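#' Synthetic gene universe
#'
#' Generates `size` unique synthetic symbols `GENE000001`, `GENE000002`,
#' ... Labels are positional, so the same size always yields the same set
#' regardless of seed; the seed argument exists for interface symmetry
#' with the samplers.
#'
#' @param size Number of genes, at least 1.
#' @param seed Unused for labels; kept for a uniform generator interface.
#' @return Character vector of `size` unique gene labels.
#' @export
make_universe <- function(size, seed = 1L) {
  if (!is.numeric(size) || length(size) != 1 || size < 1 || size != floor(size)) {
    stop("universe size must be a positive integer", call. = FALSE)
  }
  sprintf("GENE%06d", seq_len(size))
}

#' Synthetic annotation dataset
#'
#' Draws `n_sets` gene sets over a universe, each of a size sampled
#' uniformly in `size_range`, with members sampled without replacement per
#' set (sets may overlap one another). The shape mirrors curated
#' collections in which a study contributes on the order of 5-20 cluster
#' gene sets over a few thousand differentially expressed genes. The
#' dataset universe is the union of the members unless `full_universe`
#' asks for the whole input universe (emulating an expressed-gene
#' background wider than the reported sets).
#'
#' @param universe Character vector of gene labels to sample from.
#' @param n_sets Number of gene sets.
#' @param size_range Length-2 integer vector `(min, max)` of set sizes.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @param dataset_id Identifier for the dataset.
#' @param full_universe Use the whole `universe` as the dataset universe.
#' @return An `hyperora_dataset`.
#' @export
make_annotation_dataset <- function(universe, n_sets, size_range, seed = 1L,
                                    dataset_id = "synthetic",
                                    full_universe = FALSE) {
  stopifnot(length(universe) >= 1, n_sets >= 1, length(size_range) == 2)
  if (size_range[1] > size_range[2] || size_range[1] < 1 ||
      size_range[2] > length(universe)) {
    stop("infeasible set size range for a universe of ", length(universe),
         " genes", call. = FALSE)
  }
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sizes <- seq(size_range[1], size_range[2])
      sz <- if (length(sizes) == 1) sizes else sample(sizes, 1)
      gene_set(set_id = sprintf("%s_set%02d", dataset_id, i),
               members = sample(universe, sz),
               description = sprintf("synthetic gene set %d of %d", i, n_sets))
    })
    annotation_dataset(dataset_id, sets,
                       universe = if (full_universe) universe else NULL,
                       title = sprintf("synthetic dataset '%s'", dataset_id))
  })
}

#' Null query: a uniform draw from the background
#'
#' @param background Character vector of gene labels.
#' @param size Query size, `1 <= size <= length(background)`.
#' @param seed Integer seed.
#' @return Character vector of `size` genes.
#' @export
make_null_query <- function(background, size, seed = 1L) {
  if (size < 1 || size > length(background)) {
    stop("query size must lie in [1, |background|]", call. = FALSE)
  }
  withr::with_seed(seed, sample(background, size))
}

#' Query with planted enrichment for one target gene set
#'
#' Builds a query of `total` genes of which `round(planted_fraction *
#' total)` come from the target set (restricted to the background) and the
#' rest are sampled from the background outside the target — the standard
#' parameter-recovery harness for an over-representation test.
#'
#' @param background Character vector of gene labels.
#' @param target An `hyperora_gene_set` to enrich for.
#' @param total Query size.
#' @param planted_fraction Fraction of the query drawn from the target.
#' @param seed Integer seed.
#' @return Character vector of `total` genes.
#' @export
make_enriched_query <- function(background, target, total, planted_fraction,
                                seed = 1L) {
  stopifnot(inherits(target, "hyperora_gene_set"),
            planted_fraction >= 0, planted_fraction <= 1, total >= 1)
  bg_keys <- normalize_gene_id(background)$normalized_key
  in_target <- background[bg_keys %in% target$members$normalized_key]
  n_plant <- round(planted_fraction * total)
  if (n_plant > length(in_target)) {
    stop("infeasible planted fraction: need ", n_plant,
         " target genes but only ", length(in_target),
         " lie in the background", call. = FALSE)
  }
  outside <- setdiff(background, in_target)
  if (total - n_plant > length(outside)) {
    stop("background too small outside the target set", call. = FALSE)
  }
  withr::with_seed(seed, {
    c(sample(in_target, n_plant),
      if (total - n_plant > 0) sample(outside, total - n_plant))
  })
}

#' Write a demonstration fixture to a directory
#'
#' Generates a small study-shaped corpus: three annotation datasets of 11,
#' 7 and 5 gene sets over a 3348-gene universe (the shape of typical
#' curated macrophage collections, without any claim to their content), a
#' background file, a single-query list and a multi-query CSV of three
#' cluster-like lists, one of which has enrichment planted for a known
#' set. All files are plain text; generation is deterministic per seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_demo_fixture <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  universe <- make_universe(3348)
  shapes <- list(alpha = c(11, 150, 400), beta = c(7, 100, 300),
                 gamma = c(5, 80, 250))
  paths <- list()
  datasets <- list()
  for (i in seq_along(shapes)) {
    nm <- names(shapes)[i]
    sh <- shapes[[i]]
    ds <- make_annotation_dataset(universe, n_sets = sh[1],
                                  size_range = sh[2:3], seed = seed + i,
                                  dataset_id = nm)
    path <- file.path(dir, paste0(nm, ".gmt"))
    write_gmt(ds, path)
    paths[[paste0("gmt_", nm)]] <- path
    datasets[[nm]] <- ds
  }
  background <- withr::with_seed(seed, sample(universe, 2500))
  paths$background <- file.path(dir, "background.txt")
  writeLines(sort(background), paths$background)

  target <- datasets$alpha$gene_sets[[1]]
  planted <- make_enriched_query(background, target, total = 120,
                                 planted_fraction = 0.6, seed = seed + 11)
  null1 <- make_null_query(background, 120, seed = seed + 12)
  null2 <- make_null_query(background, 120, seed = seed + 13)
  paths$query <- file.path(dir, "query.txt")
  writeLines(planted, paths$query)
  paths$multi_query <- file.path(dir, "clusters.csv")
  writeLines(c("gene,list",
               paste0(planted, ",cluster1"),
               paste0(null1, ",cluster2"),
               paste0(null2, ",cluster3")),
             paths$multi_query)
  invisible(paths)
}
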