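# Independent oracles and small fixture builders shared across tests.

# Exhaustive-enumeration oracle for the hypergeometric upper tail: place the
# K annotated genes in every one of the C(N, K) ways, take the query to be
# genes 1..n (exchangeability makes the choice irrelevant), and count
# placements with at least k annotated genes in the query. Independent of
# the package's survival-function route.
enum_upper_tail <- function(N, n, K, k) {
  if (K == 0) return(if (k == 0) 1 else 0)
  placements <- utils::combn(N, K)
  hits <- colSums(placements <= n) >= k
  mean(hits)
}

# Exact big-integer rational oracle via Python's fractions module; returns
# the tail probabilities as doubles rounded only at the final division.
exact_upper_tail_py <- function(N, n, K, k) {
  cases <- data.frame(N = N, n = n, K = K, k = k)
  infile <- tempfile(fileext = ".csv")
  utils::write.csv(cases, infile, row.names = FALSE)
  script <- paste(
    "import sys, csv",
    "from fractions import Fraction",
    "from math import comb",
    "rows = list(csv.DictReader(open(sys.argv[1])))",
    "for r in rows:",
    "    N, n, K, k = (int(r[c]) for c in ('N', 'n', 'K', 'k'))",
    "    p = sum(Fraction(comb(n, i) * comb(N - n, K - i), comb(N, K))",
    "            for i in range(k, min(n, K) + 1))",
    "    print(repr(float(p)))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(infile)),
                 stdout = TRUE)
  as.numeric(out)
}

# Classical BH step-up rejection set at level alpha with m comparisons:
# reject the i smallest p-values where i is the largest rank j such that
# p_(j) <= j * alpha / m. Written directly from the step-up definition.
bh_reject_classical <- function(p, alpha, m = length(p)) {
  ord <- order(p)
  js <- which(p[ord] <= seq_along(p) * alpha / m)
  rejected <- logical(length(p))
  if (length(js) > 0) rejected[ord[seq_len(max(js))]] <- TRUE
  rejected
}

# Two-set GMT used throughout the db/query tests.
tiny_gmt <- function(lines = c("SetA\tdesc A\tg1\tg2\tg3",
                               "SetB\tdesc B\tg3\tg4")) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

write_lines_file <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# A small but non-trivial analysis fixture: one dataset, planted signal in
# the first query list.
small_fixture <- function(seed = 42L) {
  universe <- hyperora::make_universe(500)
  ds <- hyperora::make_annotation_dataset(universe, n_sets = 6,
                                          size_range = c(30, 60),
                                          seed = seed, dataset_id = "ds1",
                                          full_universe = TRUE)
  background <- universe
  target <- ds$gene_sets[[1]]
  q1 <- hyperora::make_enriched_query(background, target, total = 40,
                                      planted_fraction = 0.7,
                                      seed = seed + 1)
  q2 <- hyperora::make_null_query(background, 40, seed = seed + 2)
  collection <- hyperora::assemble_collection(
    list(planted = q1, null = q2), background)
  list(universe = universe, dataset = ds, collection = collection,
       target = target)
}
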