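test_that("hypergeometric upper tail matches hand-derived and boundary values", {
  expect_equal(hypergeom_upper_tail(10, 5, 4, 3), 11 / 42, tolerance = 1e-12)
  expect_identical(hypergeom_upper_tail(10, 5, 4, 0), 1)   # full support
  expect_identical(hypergeom_upper_tail(20, 7, 20, 7), 1)  # N = K forces k = n
  # symmetry of the hypergeometric in n and K
  cases <- expand.grid(N = c(15, 30), n = c(4, 9), K = c(5, 12))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      for (k in 0:min(n, K)) {
        expect_equal(hypergeom_upper_tail(N, n, K, k),
                     hypergeom_upper_tail(N, K, n, k), tolerance = 1e-14)
      }
    })
  }
})

test_that("parameter violations are reported by the violated inequality", {
  expect_error(hypergeom_upper_tail(10, 11, 4, 0), "n > N")
  expect_error(hypergeom_upper_tail(10, 5, 11, 0), "K > N")
  expect_error(hypergeom_upper_tail(10, 5, 4, 5), "k > min")
  expect_error(hypergeom_upper_tail(10, 5, -1, 0), "non-negative")
})

test_that("upper tail is strictly decreasing in k and equals the enumeration oracle", {
  for (N in c(8, 11)) {
    for (n in c(3, 5)) {
      for (K in c(2, 6)) {
        ks <- 0:min(n, K)
        ps <- vapply(ks, function(k) hypergeom_upper_tail(N, n, K, k),
                     numeric(1))
        # the tail is exactly 1 for every k at or below the smallest
        # achievable overlap max(0, n + K - N); strict decrease holds above it
        lower <- max(0, n + K - N)
        expect_true(all(ps[ks <= lower] == 1))
        in_support <- ks >= lower
        expect_true(all(diff(ps[in_support]) < 0))
        oracle <- vapply(ks, function(k) enum_upper_tail(N, n, K, k),
                         numeric(1))
        expect_equal(ps, oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("background resolution follows the intersect / user semantics", {
  universe <- sprintf("U%04d", 1:5000)
  bg <- c(universe[1001:5000], sprintf("X%04d", 1:3000))  # 7000, 4000 inside
  q_in <- universe[1001:1400]                             # 400 inside
  q_out <- sprintf("X%04d", 1:160)
  query <- c(q_in, q_out)                                 # 560 total
  ds <- annotation_dataset("d", list(gene_set("s", universe[1:460])),
                           universe = universe)

  res_i <- resolve_background(query, bg, ds, "intersect")
  expect_equal(length(res_i$background), 4000)
  expect_equal(length(res_i$query), 400)
  expect_true(all(res_i$query %in% res_i$background))

  res_u <- resolve_background(query, bg, ds, "user")
  expect_equal(length(res_u$background), 7000)
  expect_equal(length(res_u$query), 560)

  # background contained in the universe: intersection is the identity
  res_id <- resolve_background(universe[1:50], universe[1:100], ds, "intersect")
  expect_equal(sort(res_id$background), sort(universe[1:100]))

  # fully disjoint background flags the dataset as degenerate, not an error
  res_d <- resolve_background("Z1", c("Z1", "Z2"), ds, "intersect")
  expect_true(res_d$degenerate)
})

test_that("test_one counts the overlaps behind K and k", {
  bg <- sprintf("g%d", 1:10)
  s <- gene_set("s", c("g3", "g4"))
  t1 <- test_one(c("G1", "G2", "G3"), toupper(bg), s)
  expect_equal(t1$K, 2)
  expect_equal(t1$k, 1)
  expect_equal(t1$overlap, "G3")
  expect_equal(t1$N, 10)
  expect_equal(t1$n, 3)

  # disjoint set: k = 0 gives the upper-tail lower bound of exactly 1
  t0 <- test_one(c("G1", "G2"), toupper(bg), gene_set("s2", c("g9", "g10")))
  expect_identical(t0$p_enrich, 1)

  # K = 0 is untestable and signalled, not computed
  expect_null(test_one(c("G1"), c("G1", "G2"), gene_set("s3", "g7")))
})

test_that("bh_adjust reproduces the worked step-up vectors", {
  expect_equal(bh_adjust(0.04, m = 1), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04), m = 4), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04, 0.045), m = 5),
               c(0.025, 0.0275, 0.02 * 5 / 3, 0.045, 0.045),
               tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("enrich produces one row per testable pair with global FDR", {
  fx <- small_fixture()
  res <- enrich(fx$collection, fx$dataset, mode = "user")
  expect_s3_class(res, "hyperora_results")
  expect_equal(nrow(res), 2 * 6)  # 2 queries x 6 sets
  expect_equal(attr(res, "m"), nrow(res))
  expect_equal(res$p_deplete, 1 - res$p_enrich)
  expect_true(all(res$fdr >= res$p_enrich & res$fdr <= 1))
  expect_equal(res$fdr, bh_adjust(res$p_enrich, m = attr(res, "m")))
  expect_equal(vapply(res$overlap_genes, length, integer(1)), res$k)
  # ordering: dataset, then gene-set line order, then query order
  expect_equal(res$set_id[1:2], rep(names(fx$dataset$gene_sets)[1], 2))
  expect_equal(res$query[1:2], c("planted", "null"))
  # the planted target attains the smallest p for the planted query
  planted <- res[res$query == "planted", ]
  expect_equal(planted$set_id[which.min(planted$p_enrich)],
               fx$target$set_id)
})

test_that("a query identical to a gene set attains the minimal p among equal-sized sets", {
  universe <- make_universe(300)
  sets <- lapply(1:5, function(i) {
    gene_set(sprintf("s%d", i), universe[((i - 1) * 40 + 1):(i * 40)])
  })
  ds <- annotation_dataset("d", sets, universe = universe)
  col <- assemble_collection(list(q = universe[1:40]), universe)
  res <- enrich(col, ds, mode = "user")
  expect_equal(res$set_id[which.min(res$p_enrich)], "s1")
  expect_equal(res$k[res$set_id == "s1"], 40)
})

test_that("intersect-mode results ignore background genes outside every universe", {
  fx <- small_fixture()
  res1 <- enrich(fx$collection, fx$dataset, mode = "intersect")

  padding <- sprintf("PAD%05d", 1:400)
  bg2 <- c(fx$collection$background$raw_label, padding)
  col2 <- assemble_collection(
    stats::setNames(lapply(fx$collection$queries, function(q) q$raw_label),
                    names(fx$collection$queries)),
    bg2)
  res2 <- enrich(col2, fx$dataset, mode = "intersect")
  expect_identical(res1$p_enrich, res2$p_enrich)
  expect_identical(res1$N, res2$N)
  expect_identical(res1$fdr, res2$fdr)
})

test_that("K against the intersected background equals the user-background overlap", {
  # gene sets live inside the universe, so intersecting the background with
  # the universe cannot change which annotated genes it contains
  fx <- small_fixture()
  bg <- fx$collection$background$normalized_key
  for (s in fx$dataset$gene_sets) {
    eff <- resolve_background(fx$collection$queries$planted$normalized_key,
                              bg, fx$dataset, "intersect")
    K_intersected <- sum(s$members$normalized_key %in% eff$background)
    K_user <- sum(s$members$normalized_key %in% bg)
    expect_equal(K_intersected, K_user)
  }
})

test_that("all-degenerate intersect runs advise switching to user mode", {
  ds <- annotation_dataset("d", list(gene_set("s", c("a1", "a2"))))
  col <- assemble_collection(list(q = c("z1", "z2")), c("z1", "z2", "z3"))
  expect_error(enrich(col, ds, mode = "intersect"), "user")
})
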