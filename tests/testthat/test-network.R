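make_two_set_datasets <- function() {
  list(annotation_dataset("d1", list(gene_set("A", c("a", "b", "c", "d")),
                                     gene_set("B", c("c", "d", "e", "f")))),
       annotation_dataset("d2", list(gene_set("C", c("x", "y")))))
}

test_that("edge weights are the Jaccard index with thresholding", {
  g <- build_graph(make_two_set_datasets(), min_weight = 0)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)  # C is disjoint from A and B
  e <- igraph::as_data_frame(g, "edges")
  expect_equal(e$weight, 2 / 6, tolerance = 1e-12)

  # identical sets have weight exactly 1
  same <- list(annotation_dataset("d", list(gene_set("A", c("a", "b")),
                                            gene_set("B", c("a", "b")))))
  g1 <- build_graph(same, min_weight = 0)
  expect_equal(igraph::as_data_frame(g1, "edges")$weight, 1)

  # raising min_weight never adds edges
  g_lo <- build_graph(make_two_set_datasets(), min_weight = 0.05)
  g_hi <- build_graph(make_two_set_datasets(), min_weight = 0.5)
  expect_lte(igraph::ecount(g_hi), igraph::ecount(g_lo))
  expect_equal(igraph::ecount(g_hi), 0)  # 1/3 <= 0.5 is filtered out
})

test_that("overlap-coefficient weighting is available behind a flag", {
  ds <- list(annotation_dataset("d", list(gene_set("A", c("a", "b")),
                                          gene_set("B", c("a", "b", "c", "d")))))
  gj <- build_graph(ds, min_weight = 0, weight_method = "jaccard")
  go <- build_graph(ds, min_weight = 0, weight_method = "overlap")
  expect_equal(igraph::as_data_frame(gj, "edges")$weight, 0.5)
  expect_equal(igraph::as_data_frame(go, "edges")$weight, 1)  # A within B
})

test_that("graph construction is deterministic and carries dataset grouping", {
  fx <- small_fixture()
  g1 <- build_graph(list(fx$dataset))
  g2 <- build_graph(list(fx$dataset))
  expect_identical(igraph::as_data_frame(g1, "both"),
                   igraph::as_data_frame(g2, "both"))
  expect_equal(unique(igraph::V(g1)$dataset), "ds1")
  expect_equal(igraph::V(g1)$size,
               vapply(fx$dataset$gene_sets, function(s) nrow(s$members),
                      integer(1), USE.NAMES = FALSE))
})

test_that("overlay maps -log10 p onto tested nodes and is replaceable", {
  fx <- small_fixture()
  res <- enrich(fx$collection, fx$dataset, mode = "user")
  g <- build_graph(list(fx$dataset), min_weight = 0)
  g1 <- overlay_query(g, res, "planted")
  sub <- res[res$query == "planted", ]
  expect_equal(igraph::V(g1)$score,
               -log10(sub$p_enrich[match(igraph::V(g1)$set_id, sub$set_id)]))
  # p of 1 gives score 0; p of 0.01 gives 2
  expect_equal(unname((-log10(0.01))), 2)

  g2 <- overlay_query(g1, res, "null")
  expect_identical(igraph::as_data_frame(g2, "edges"),
                   igraph::as_data_frame(g1, "edges"))
  expect_equal(g2$query, "null")

  expect_error(overlay_query(g, res, "nope"), "planted")
})

test_that("graphml export round-trips nodes, edges and weights", {
  fx <- small_fixture()
  res <- enrich(fx$collection, fx$dataset, mode = "user")
  g <- overlay_query(build_graph(list(fx$dataset), min_weight = 0), res,
                     "planted")
  path <- tempfile(fileext = ".graphml")
  export_graph(g, "graphml", path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_equal(igraph::E(back)$weight, igraph::E(g)$weight, tolerance = 1e-9)
  expect_equal(igraph::V(back)$score, igraph::V(g)$score, tolerance = 1e-9)
  expect_equal(igraph::V(back)$dataset, igraph::V(g)$dataset)
})

test_that("cytoscape json export carries scores and survives re-parsing", {
  fx <- small_fixture()
  res <- enrich(fx$collection, fx$dataset, mode = "user")
  g <- overlay_query(build_graph(list(fx$dataset), min_weight = 0), res,
                     "planted")
  path <- tempfile(fileext = ".json")
  export_graph(g, "cytoscape_json", path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- parsed$elements$nodes
  edges <- parsed$elements$edges
  expect_equal(length(nodes), igraph::vcount(g))
  expect_equal(length(edges), igraph::ecount(g))
  expect_true(all(vapply(nodes, function(n) is.numeric(n$data$score),
                         logical(1))))
  expect_equal(vapply(edges, function(e) e$data$weight, numeric(1)),
               igraph::E(g)$weight, tolerance = 1e-9)

  expect_error(export_graph(g, "dot", tempfile()), "arg")
})

test_that("a graph whose edges all fall below threshold still exports", {
  ds <- make_two_set_datasets()
  g <- build_graph(ds, min_weight = 0.9)
  expect_equal(igraph::ecount(g), 0)
  path <- tempfile(fileext = ".graphml")
  export_graph(g, "graphml", path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 0)
})
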