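write_edges <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("edge reading collapses duplicates, rescales, drops self-loops", {
  p <- write_edges(data.frame(node1 = c("A", "B", "C"),
                              node2 = c("B", "A", "C"),
                              combined_score = c(900, 900, 500)))
  expect_warning(g <- read_interaction_edges(p), "self-loop")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.9)
  expect_warning(g2 <- read_interaction_edges(p, score_cutoff = 0.95),
                 "self-loop")
  expect_equal(igraph::ecount(g2), 0)
  # unit-scale input left untouched
  p2 <- write_edges(data.frame(node1 = "A", node2 = "B",
                               combined_score = 0.7))
  expect_equal(igraph::E(read_interaction_edges(p2))$weight, 0.7)
})

test_that("connectivity filter keeps genes with at least one induced edge", {
  p <- write_edges(data.frame(node1 = c("A", "C"), node2 = c("B", "D"),
                              combined_score = c(800, 700)))
  g <- read_interaction_edges(p)
  expect_equal(connected_candidates(g, c("A", "B", "X")), c("A", "B"))
  # C-D edge leaves the induced subgraph when D is not a candidate
  expect_equal(connected_candidates(g, c("C", "A")), character(0))
  expect_equal(connected_candidates(g, c("A", "B", "C", "D")),
               c("A", "B", "C", "D"))
})

test_that("MCC matches hand-derived values on canonical graphs", {
  tri <- igraph::make_graph(~ A - B, B - C, A - C)
  expect_equal(mcc_scores(tri)$mcc, rep(2, 3))
  path <- igraph::make_graph(~ A - B, B - C)
  sc <- mcc_scores(path)
  expect_equal(sc$mcc[sc$node == "B"], 2)
  expect_equal(sc$mcc[sc$node %in% c("A", "C")], c(1, 1))
  two_tri <- igraph::make_graph(~ A - B, B - C, A - C, D - E, E - F, D - F)
  expect_equal(mcc_scores(two_tri)$mcc, rep(2, 6))
  # complete graphs: every node scores (m-1)!
  for (m in 3:6) {
    km <- igraph::make_full_graph(m)
    igraph::V(km)$name <- letters[1:m]
    expect_equal(mcc_scores(km)$mcc, rep(factorial(m - 1), m))
  }
})

test_that("MCC equals the brute-force enumerator on random graphs", {
  for (i in 1:20) {
    set.seed(i)
    nv <- sample(4:10, 1)
    nodes <- sprintf("n%02d", 1:nv)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.4
    edges <- pairs[keep, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges), directed = FALSE,
      vertices = data.frame(name = nodes))
    got <- mcc_scores(g)
    ora <- mcc_bruteforce(nodes, edges)
    expect_equal(setNames(got$mcc, got$node)[nodes], ora)
    # clique-sum identity
    cl_sizes <- lengths(igraph::max_cliques(g, min = 2))
    expect_equal(sum(got$mcc), sum(cl_sizes * factorial(cl_sizes - 1)))
  }
})

test_that("top central nodes use lexicographic tie-breaks and report overlap", {
  path <- igraph::make_graph(~ A - B, B - C)
  sc <- mcc_scores(path)
  expect_equal(top_central(sc, 1)$nodes, "B")
  expect_equal(top_central(sc, 3)$nodes, c("B", "A", "C"))
  res <- top_central(sc, 2, predictors = c("C", "B", "Z"))
  expect_equal(res$overlap, "B")
  expect_equal(res$n_overlap, 1L)
  expect_error(top_central(sc, 4), "between 1 and")
  tied <- data.frame(node = c("d", "b", "a"), mcc = c(1, 1, 1))
  expect_equal(top_central(tied, 2)$nodes, c("a", "b"))
})
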