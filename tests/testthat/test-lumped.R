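test_that("lumped complete-graph statistics match closed forms", {
  for (n in c(2, 6, 10, 50)) for (r in c(0.5, 1, 1.1, 2)) {
    st <- complete_graph_stats(n, r)
    expect_equal(st$rho, moran_rho_closed_form(n, r), tolerance = 1e-12)
  }
  expect_equal(complete_graph_stats(6, 1)$cond_fix_time, 25,
               tolerance = 1e-9)  # (N - 1)^2 neutral fixation time
})

test_that("lumped complete-graph times track the large-N asymptotics", {
  r <- 1.1
  n <- 2000
  st <- complete_graph_stats(n, r)
  expect_gt(st$absorb_time / ((r + 1) / r * n * log(n)), 0.8)
  expect_lt(st$absorb_time / ((r + 1) / r * n * log(n)), 1.2)
  expect_gt(st$cond_fix_time / ((r + 1) / (r - 1) * n * log(n)), 0.5)
  expect_lt(st$cond_fix_time / ((r + 1) / (r - 1) * n * log(n)), 1.5)
})

test_that("lumped solvers agree with the full-state engine", {
  r_grid <- c(1, 1.1, 2)
  for (r in r_grid) {
    # complete
    sol <- solve_fixation(replacement_kernel(make_complete(7)), r)
    st <- complete_graph_stats(7, r)
    expect_equal(mean(sol$rho), st$rho, tolerance = 1e-8)
    expect_equal(mean(sol$absorb_time), st$absorb_time, tolerance = 1e-8)
    expect_equal(sol$cond_fix_time[1], st$cond_fix_time, tolerance = 1e-8)
    for (scheme in c("uniform", "temperature")) {
      # star
      Ws <- replacement_kernel(make_star(8))
      agg <- aggregate_solution(solve_fixation(Ws, r), scheme, Ws)
      st <- star_stats(8, r, scheme)
      expect_equal(agg$rho, st$rho, tolerance = 1e-8)
      expect_equal(agg$cond_fix_time, st$cond_fix_time, tolerance = 1e-8)
      expect_equal(agg$absorb_time, st$absorb_time, tolerance = 1e-8)
      # balanced and weighted bipartite
      for (loop in c(0, 3)) {
        g <- make_complete_bipartite(6, 2, loop)
        W <- replacement_kernel(g)
        agg <- aggregate_solution(solve_fixation(W, r), scheme, W)
        bp <- bipartite_stats(6, 2, loop, r, scheme)
        expect_equal(agg$rho, bp$rho, tolerance = 1e-8)
        expect_equal(agg$cond_fix_time, bp$cond_fix_time, tolerance = 1e-8)
        expect_equal(agg$absorb_time, bp$absorb_time, tolerance = 1e-8)
      }
    }
  }
})

test_that("the star is the (n-1, 1) special case of the bipartite chain", {
  for (init in c("uniform", "temperature")) {
    st <- star_stats(12, 1.3, init)
    bp <- bipartite_stats(11, 1, 0, 1.3, init)
    expect_equal(st$rho, bp$rho)
    expect_equal(st$cond_fix_time, bp$cond_fix_time)
  }
})

test_that("star amplification approaches 1 - 1/r^2 for large populations", {
  r <- 1.1
  st <- star_stats(2000, r, "uniform")
  expect_lt(abs(st$rho - (1 - 1 / r^2)), 0.01)
  # fixation time of order N^2 log N: bounded ratio across sizes
  ratios <- vapply(c(500, 1000, 2000), function(n)
    star_stats(n, r, "uniform")$cond_fix_time / (n^2 * log(n)), numeric(1))
  expect_lt(max(ratios) / min(ratios), 2)
})

test_that("balanced bipartite fixation probability tends to 1 - 1/r^2", {
  r <- 1.1
  bp <- bipartite_stats(1000, 32, 0, r, "uniform")
  expect_lt(abs(bp$rho - (1 - 1 / r^2)), 0.02)
})

test_that("regular bipartite graphs are isothermal under temperature init", {
  bp <- bipartite_stats(4, 4, 0, 1.1, "temperature")
  ck <- complete_graph_stats(8, 1.1)
  expect_equal(bp$rho, ck$rho, tolerance = 1e-8)
})

test_that("weighted bipartite temperature-init rho rises monotonically", {
  r <- 1.1
  rhos <- vapply(c(100, 200, 400, 800), function(N)
    bipartite_stats(N, round(sqrt(N)), N^0.75 - N^0.5, r,
                    "temperature")$rho, numeric(1))
  expect_true(all(diff(rhos) > 0))
  expect_true(all(rhos < 1 - 1 / r^2))
})

test_that("step-counting conventions differ only in hold steps", {
  with_holds <- bipartite_stats(6, 2, 3, 1.1, "uniform")
  jumps_only <- bipartite_stats(6, 2, 3, 1.1, "uniform",
                                count_holds = FALSE)
  expect_equal(with_holds$rho, jumps_only$rho, tolerance = 1e-12)
  expect_lt(jumps_only$cond_fix_time, with_holds$cond_fix_time)
  expect_lt(jumps_only$absorb_time, with_holds$absorb_time)
})

test_that("weighted-bipartite time scaling depends on the step convention", {
  # counting every Moran step the fixation time grows like N^1.5 log N;
  # counting only type-changing jumps it grows like N log N
  sizes <- c(100, 200, 400, 800)
  ratios_all <- numeric(0); ratios_jump <- numeric(0)
  for (N in sizes) {
    s <- round(sqrt(N)); L <- N^0.75 - N^0.5
    wh <- bipartite_stats(N, s, L, 1.1, "temperature")
    wj <- bipartite_stats(N, s, L, 1.1, "temperature", count_holds = FALSE)
    ratios_all <- c(ratios_all, wh$cond_fix_time / (N^1.5 * log(N)))
    ratios_jump <- c(ratios_jump, wj$cond_fix_time / (N * log(N)))
  }
  expect_lt(max(ratios_all) / min(ratios_all), 2)
  expect_lt(max(ratios_jump) / min(ratios_jump), 2)
})

test_that("birth-death chain helper validates input", {
  expect_error(bd_chain_stats(c(0.5, 0.5), c(0.6, 0.6)), "invalid")
  expect_error(bd_chain_stats(c(0.5), c(0.2, 0.2)), "equal length")
  expect_error(bipartite_stats(2, 4, 0, 1.1), "m >= s")
  expect_error(bipartite_stats(100, 10, 0, 1.1, max_states = 100), "large")
})
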