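test_that("row_normalize divides positive rows and keeps zero rows", {
  expect_equal(row_normalize(matrix(c(0, 2, 2, 0), 2, byrow = TRUE)),
               matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  A <- matrix(c(0, 1, 3,
                0, 0, 0,
                1, 1, 0), 3, byrow = TRUE)
  expect_equal(row_normalize(A),
               matrix(c(0, .25, .75,
                        0, 0, 0,
                        .5, .5, 0), 3, byrow = TRUE))
  Z <- matrix(0, 3, 3)
  expect_equal(row_normalize(Z), Z)
  expect_error(row_normalize(matrix(c(1, -1, 0, 1), 2)), "negative")
  # sparse input stays sparse and gets the same values
  S <- Matrix::Matrix(A, sparse = TRUE)
  expect_s4_class(row_normalize(S), "Matrix")
  expect_equal(as.matrix(row_normalize(S)), row_normalize(A),
               ignore_attr = TRUE)
})

row_of <- function(tm, layer, id) {
  i <- which(tm$order$layer == layer & tm$order$id == id)
  r <- tm$matrix[i, ]
  names(r) <- paste(tm$order$layer, tm$order$id, sep = ":")
  r
}

test_that("rows split mass 1-lambda intra / lambda per linked foreign layer", {
  # g1: intra edge to g2 plus one bipartite link to d1 (one foreign layer)
  g <- weighted_network(edges = data.frame(from = "g1", to = "g2", weight = 1),
                        layer = "G")
  p1 <- weighted_network(nodes = "d1", layer = "P1")
  p2 <- weighted_network(nodes = "h1", layer = "P2")
  hg <- assemble(list(g, p1, p2),
                 list(bipartite_links(data.frame(a = "g1", b = "d1"), "G", "P1")))
  tm <- build_transition(hg, transition_config(lambda = 0.5))
  r <- row_of(tm, "G", "g1")
  expect_equal(unname(r[c("G:g2", "P1:d1")]), c(0.5, 0.5))
  expect_equal(sum(r), 1)
  # g2 has intra only: full mass back to g1
  expect_equal(unname(row_of(tm, "G", "g2")["G:g1"]), 1)
  # h1 is fully isolated: self-loop
  expect_equal(unname(row_of(tm, "P2", "h1")["P2:h1"]), 1)
})

test_that("a node with only bipartite links splits 1/f per foreign layer", {
  g <- weighted_network(nodes = "g1", layer = "G")
  p1 <- weighted_network(nodes = "d1", layer = "P1")
  p2 <- weighted_network(nodes = "h1", layer = "P2")
  hg <- assemble(list(g, p1, p2),
                 list(bipartite_links(data.frame(a = "g1", b = "d1"), "G", "P1"),
                      bipartite_links(data.frame(a = "g1", b = "h1"), "G", "P2")))
  tm <- build_transition(hg, transition_config(lambda = 0.5))
  r <- row_of(tm, "G", "g1")
  expect_equal(unname(r[c("P1:d1", "P2:h1")]), c(0.5, 0.5))
})

test_that("bipartite weights shape the within-layer cross distribution", {
  g <- weighted_network(edges = data.frame(from = "g1", to = "g2", weight = 2),
                        layer = "G")
  p1 <- weighted_network(nodes = c("d1", "d2"), layer = "P1")
  p2 <- weighted_network(nodes = "h1", layer = "P2")
  hg <- assemble(list(g, p1, p2),
                 list(bipartite_links(
                   data.frame(a = c("g1", "g1"), b = c("d1", "d2"),
                              weight = c(3, 1)), "G", "P1")))
  tm <- build_transition(hg, transition_config(lambda = 0.4))
  r <- row_of(tm, "G", "g1")
  expect_equal(unname(r[c("G:g2", "P1:d1", "P1:d2")]),
               c(0.6, 0.4 * 0.75, 0.4 * 0.25))
})

test_that("every row of M sums to 1 on random synthetic graphs", {
  for (seed in 1:5) {
    for (lam in c(0, 0.3, 1)) {
      tm <- build_transition(small_gen(seed)$graph, transition_config(lam))
      expect_true(all(abs(Matrix::rowSums(tm$matrix) - 1) < 1e-12))
      expect_true(all(tm$matrix@x >= 0))
    }
  }
})

test_that("lambda = 0 confines walkers with intra edges to their layer", {
  gen <- small_gen(3)
  tm <- build_transition(gen$graph, transition_config(lambda = 0))
  for (pair in list(c("G", "P1"), c("G", "P2"), c("P1", "P2"))) {
    blk <- transition_block(tm, pair[1], pair[2])
    # only rows without any intra-layer edge may leave the layer
    nw <- gen$graph$networks[[pair[1]]]
    has_intra <- gen$graph$order$id[gen$graph$order$layer == pair[1]] %in%
      unlist(nw$edges[c("from", "to")])
    expect_true(all(Matrix::rowSums(blk)[has_intra] == 0))
  }
})

test_that("transition matrix is invariant to input file line order", {
  gen <- small_gen(11)
  hg1 <- gen$graph
  # rebuild the same graph from shuffled edge lists
  shuffle <- function(nw) {
    ed <- nw$edges[sample(nrow(nw$edges)), , drop = FALSE]
    weighted_network(nodes = nw$nodes, edges = ed, layer = nw$layer)
  }
  set.seed(99)
  hg2 <- assemble(lapply(hg1$networks, shuffle),
                  lapply(hg1$bipartite, function(bp)
                    bipartite_links(bp$links[sample(nrow(bp$links)), ],
                                    bp$layer_a, bp$layer_b)))
  m1 <- build_transition(hg1)$matrix
  m2 <- build_transition(hg2)$matrix
  expect_identical(as.matrix(m1), as.matrix(m2))
})

test_that("transition matrix dumps to MatrixMarket and reloads", {
  tm <- build_transition(tiny_hg())
  path <- withr::local_tempfile(fileext = ".mtx")
  write_transition_mtx(tm, path)
  back <- Matrix::readMM(path)
  expect_equal(as.matrix(back), as.matrix(tm$matrix), ignore_attr = TRUE)
})
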