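test_that("temperatures match the replacement-rate formula", {
  Wk <- replacement_kernel(make_complete(6))
  expect_equal(temperature(Wk), rep(1 / 6, 6))
  Ws <- replacement_kernel(make_star(8))
  t8 <- temperature(Ws)
  expect_equal(t8[1], 7 / 8)
  expect_equal(t8[2:8], rep(1 / 56, 7))
  for (g in list(make_cycle(5), make_weighted_bipartite(20, 0.5),
                 random_connected_graph(8, 2)))
    expect_equal(sum(temperature(replacement_kernel(g))), 1,
                 tolerance = 1e-12)
})

test_that("self-loop handling in temperatures is switchable", {
  W <- replacement_kernel(make_complete_bipartite(4, 2, 2))
  t_in <- temperature(W, include_selfloops = TRUE)
  t_ex <- temperature(W, include_selfloops = FALSE)
  expect_equal(sum(t_in), 1); expect_equal(sum(t_ex), 1)
  expect_gt(t_in[1], t_ex[1])  # large-part vertex loses its self-loop mass
})

test_that("aggregation follows the scheme-weighted definitions", {
  g <- make_star(6); W <- replacement_kernel(g)
  sol <- solve_fixation(W, 1.2)
  un <- aggregate_solution(sol, "uniform", W)
  expect_equal(un$rho, mean(sol$rho), tolerance = 1e-12)
  expect_equal(un$absorb_time, mean(sol$absorb_time), tolerance = 1e-12)
  # fixation-weighted, not the plain mean, for conditional time
  expect_equal(un$cond_fix_time,
               sum(sol$rho * sol$cond_fix_time) / sum(sol$rho),
               tolerance = 1e-12)
  mn <- aggregate_solution(sol, "uniform", W, tau_aggregation = "mean")
  expect_equal(mn$cond_fix_time, mean(sol$cond_fix_time), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(un$cond_fix_time, mn$cond_fix_time)))

  tp <- aggregate_solution(sol, "temperature", W)
  tv <- temperature(W)
  expect_equal(tp$rho, sum(tv * sol$rho), tolerance = 1e-12)

  # point mass recovers the per-vertex values
  pm <- aggregate_solution(sol, c(1, rep(0, 5)), W)
  expect_equal(pm$rho, sol$rho[1])
  expect_equal(pm$cond_fix_time, sol$cond_fix_time[1])

  # regular graph: uniform and temperature coincide
  gc <- make_cycle(6); Wc <- replacement_kernel(gc)
  sc <- solve_fixation(Wc, 1.2)
  expect_equal(aggregate_solution(sc, "uniform", Wc)$rho,
               aggregate_solution(sc, "temperature", Wc)$rho,
               tolerance = 1e-12)
})

test_that("neutral uniform aggregation gives exactly 1/N", {
  g <- random_connected_graph(7, 9); W <- replacement_kernel(g)
  agg <- aggregate_solution(solve_fixation(W, 1), "uniform", W)
  expect_equal(agg$rho, 1 / 7, tolerance = 1e-10)
})

test_that("fixation-weighted time matches truncated trajectory summation", {
  g <- make_star(3); W <- replacement_kernel(g)
  r <- 1.3
  bf <- brute_force_cond_fix_time(W, r, rep(1 / 3, 3))
  expect_lt(bf$tail, 1e-14)
  agg <- aggregate_solution(solve_fixation(W, r), "uniform", W)
  expect_equal(agg$rho, bf$rho, tolerance = 1e-10)
  expect_equal(agg$cond_fix_time, bf$tau, tolerance = 1e-8)
})

test_that("effective rate follows 1/(t1 + t2) and its monotonicities", {
  # N = 100, mu = 1e-3, rho = 0.1: t1 = 1/(N mu rho) = 100 generations
  expect_equal(effective_rate(100, 1e-3, 0.1, 1e-9),
               1 / (100 + 1e-9 / 100), tolerance = 1e-12)
  # high-mutation limit: rate -> N / tau
  expect_equal(effective_rate(100, 1e9, 0.2, 500), 100 / 500,
               tolerance = 1e-6)
  r1 <- effective_rate(100, 1e-4, 0.1, 300)
  expect_gt(effective_rate(100, 1e-4, 0.2, 300), r1)
  expect_gt(effective_rate(100, 2e-4, 0.1, 300), r1)
  expect_lt(effective_rate(100, 1e-4, 0.1, 600), r1)
  expect_error(effective_rate(100, -1, 0.1, 300), "positive")
})

test_that("pareto front keeps exactly the non-dominated records", {
  rec <- data.frame(rho = c(0.1, 0.2, 0.2, 0.3, 0.15),
                    fix_time_steps = c(10, 20, 15, 40, 60))
  pf <- pareto_front(rec)
  # (0.1,10), (0.2,15), (0.3,40) survive; (0.2,20) dominated by (0.2,15);
  # (0.15,60) dominated by (0.2,15)
  expect_equal(sort(pf$rho), c(0.1, 0.2, 0.3))
  expect_equal(pf$fix_time_steps[pf$rho == 0.2], 15)
  # idempotence
  expect_equal(pareto_front(pf), pf)
  # single record survives; empty input stays empty
  expect_equal(nrow(pareto_front(rec[2, ])), 1)
  expect_equal(nrow(pareto_front(rec[0, ])), 0)
  # exact ties in rho: only the faster survives
  tie <- data.frame(rho = c(0.2, 0.2), fix_time_steps = c(30, 20))
  expect_equal(pareto_front(tie)$fix_time_steps, 20)
})

test_that("absorption lower bound evaluates (rho/r) N log N", {
  expect_equal(absorption_lower_bound(0.5, 0.5, 10), 10 * log(10))
  expect_equal(absorption_lower_bound(1e-9, 1, 10), 1e-9 * 10 * log(10))
  expect_error(absorption_lower_bound(0, 1, 10), "rho")
})
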