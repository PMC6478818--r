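test_that("constructors produce the expected edge structure", {
  expect_equal(nrow(make_complete(8)$edges), 28)
  expect_equal(nrow(make_complete(3)$edges), 3)
  expect_error(make_complete(1), "n >= 2")

  st <- make_star(4)
  expect_true(all(st$edges$from == 1))
  expect_setequal(st$edges$to, 2:4)
  expect_error(make_star(2), "n >= 3")

  cy <- make_cycle(8)
  deg <- tabulate(c(cy$edges$from, cy$edges$to), nbins = 8)
  expect_true(all(deg == 2))
  expect_equal(nrow(cy$edges), 8)
})

test_that("replacement kernel rows are normalized per source", {
  for (g in list(make_complete(5), make_star(6), make_cycle(4),
                 make_complete_bipartite(4, 2, 2),
                 make_weighted_bipartite(10, 0.5))) {
    W <- replacement_kernel(g)
    expect_equal(rowSums(W), rep(1, g$n), tolerance = 1e-12)
  }
  W2 <- replacement_kernel(make_complete(2))
  expect_equal(W2, matrix(c(0, 1, 1, 0), 2))
  Wk <- replacement_kernel(make_complete(3))
  expect_true(all(Wk[row(Wk) != col(Wk)] == 0.5))
  Ws <- replacement_kernel(make_star(4))
  expect_equal(unname(Ws[2, ]), c(1, 0, 0, 0))  # leaf -> center point mass
  expect_equal(unname(Ws[1, 2:4]), rep(1 / 3, 3))
})

test_that("bipartite families follow the part-size and self-loop rules", {
  b <- make_complete_bipartite(4, 2, 2)
  W <- replacement_kernel(b)
  expect_equal(W[1, 1], 0.5)            # self w.p. l/(l+s) = 2/4
  expect_equal(unname(W[1, 5:6]), c(0.25, 0.25))
  expect_equal(unname(W[5, 1:4]), rep(0.25, 4))
  expect_error(make_complete_bipartite(2, 4), "parts swapped")
  expect_error(make_complete_bipartite(4, 2, -1), "nonnegative")

  expect_equal(make_balanced_bipartite(8, 1 / 3)$n, 8 + 4)   # 8^(2/3) = 4
  expect_equal(make_balanced_bipartite(100, 0.5)$n, 110)
  expect_equal(make_balanced_bipartite(1000, 0.1)$n, 1000 + 501)

  w1 <- make_weighted_bipartite(100, 1)
  expect_equal(w1$n, 101)
  loops <- w1$edges[w1$edges$from == w1$edges$to, ]
  expect_equal(nrow(loops), 100)
  expect_equal(loops$weight[1], 9)      # 100^0.5 - 1
  w2 <- make_weighted_bipartite(100, 0.5)
  expect_equal(w2$edges$weight[w2$edges$from == w2$edges$to][1],
               100^0.75 - 10, tolerance = 1e-12)
  # migration probability to the small part ~ N^(-alpha/2)
  Ww <- replacement_kernel(w2)
  expect_equal(sum(Ww[1, 101:110]), 10 / 100^0.75, tolerance = 1e-12)
})

test_that("random constructors are seeded and connected", {
  t1 <- make_random_tree(100, seed = 7)
  t2 <- make_random_tree(100, seed = 7)
  expect_identical(t1$edges, t2$edges)
  expect_equal(nrow(t1$edges), 99)
  expect_false(identical(t1$edges, make_random_tree(100, seed = 8)$edges))

  e1 <- make_erdos_renyi(20, 0.2, seed = 3)
  e2 <- make_erdos_renyi(20, 0.2, seed = 3)
  expect_identical(e1$edges, e2$edges)
  ig <- as_igraph(e1)
  expect_true(igraph::is_connected(ig))
  expect_error(make_erdos_renyi(10, 0, seed = 1, max_retries = 10),
               "connected")

  s0 <- make_star_plus_edges(8, 0, seed = 1)
  expect_equal(nrow(s0$edges), nrow(make_star(8)$edges))
  s3 <- make_star_plus_edges(8, 3, seed = 1)
  expect_equal(nrow(s3$edges), 7 + 3)
  expect_equal(anyDuplicated(paste(pmin(s3$edges$from, s3$edges$to),
                                   pmax(s3$edges$from, s3$edges$to))), 0)
  c2 <- make_cycle_plus_edges(10, 2, seed = 5)
  expect_equal(nrow(c2$edges), 12)
})

test_that("graph construction rejects invalid input", {
  expect_error(weighted_graph(3, data.frame(from = 1, to = 2, weight = 0)),
               "positive")
  expect_error(weighted_graph(4, data.frame(from = c(1, 3), to = c(2, 4),
                                            weight = 1)),
               "connected")
  # self-loops alone do not connect
  expect_error(weighted_graph(2, data.frame(from = c(1, 2), to = c(1, 2),
                                            weight = 1)),
               "connected")
})

test_that("graph6 and TSV round trips preserve the kernel", {
  for (g in list(make_star(8), make_complete(5), make_cycle(6))) {
    g2 <- graph6_to_graph(graph_to_graph6(g))
    expect_true(igraph::isomorphic(as_igraph(g), as_igraph(g2)))
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  g <- make_complete_bipartite(4, 2, 1.5)
  write_graph_tsv(g, tsv)
  hdr <- readLines(tsv, n = 1)
  expect_equal(hdr, "source\ttarget\tweight")
  g2 <- read_graph_tsv(tsv)
  expect_equal(replacement_kernel(g2), replacement_kernel(g),
               tolerance = 1e-12)
})

test_that("enumeration agrees with brute force and the analytic census", {
  expect_equal(length(enumerate_connected_graphs(3)), 2)
  expect_equal(length(enumerate_connected_graphs(4)), 6)
  for (n in 3:5) {
    expect_equal(length(enumerate_connected_graphs(n)),
                 brute_force_connected_count(n))
    expect_equal(count_connected_graphs(n), brute_force_connected_count(n))
  }
  expect_equal(count_connected_graphs(7), 853)
  expect_equal(length(enumerate_connected_graphs(7)), 853)
})

test_that("enumerated representatives are pairwise non-isomorphic", {
  gs <- enumerate_connected_graphs(5)
  igs <- lapply(gs, as_igraph)
  for (i in seq_along(igs)[-1])
    for (j in seq_len(i - 1))
      expect_false(igraph::isomorphic(igs[[i]], igs[[j]], method = "vf2"))
})
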