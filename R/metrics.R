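#' Vertex temperatures (replacement rates)
#'
#' The temperature of a vertex is its replacement rate,
#' `t(v) = (1/N) sum_u w(u, v)`: how often an offspring produced anywhere
#' lands on `v`. Temperatures always sum to one. By default the self-loop
#' contribution `w(v, v)` counts towards `t(v)` (a self-replacement is a
#' replacement event); set `include_selfloops = FALSE` to drop it and
#' renormalize, which treats only cross-vertex replacements as mutagenic.
#'
#' @param kernel Row-stochastic replacement kernel.
#' @param include_selfloops Count `w(v, v)` in `t(v)`?
#' @return Numeric vector of temperatures, summing to 1.
#' @export
#' @examples
#' temperature(replacement_kernel(make_star(8)))  # center 7/8, leaves 1/56
temperature <- function(kernel, include_selfloops = TRUE) {
  W <- kernel
  if (!include_selfloops) diag(W) <- 0
  t_raw <- colSums(W) / nrow(W)
  t_raw / sum(t_raw)
}

#' Mutant-placement distribution of an initialization scheme
#'
#' Uniform initialization models mutants arising spontaneously (any vertex
#' equally likely); temperature initialization models mutants arising
#' during reproduction (a vertex is hit proportionally to its replacement
#' rate).
#'
#' @param scheme `"uniform"`, `"temperature"`, or a probability vector
#'   over vertices (returned unchanged after normalization).
#' @param kernel Replacement kernel (needed for `"temperature"`).
#' @param include_selfloops Passed to [temperature()].
#' @return Probability vector over vertices.
#' @export
init_distribution <- function(scheme, kernel,
                              include_selfloops = TRUE) {
  if (is.numeric(scheme)) {
    if (any(scheme < 0) || sum(scheme) <= 0) stop("invalid placement weights")
    return(scheme / sum(scheme))
  }
  scheme <- match.arg(scheme, c("uniform", "temperature"))
  n <- nrow(kernel)
  if (scheme == "uniform") rep(1 / n, n)
  else temperature(kernel, include_selfloops = include_selfloops)
}

#' Aggregate a per-vertex fixation solution under an initialization scheme
#'
#' Fixation probability and absorption time aggregate linearly:
#' `rho = sum_v pi(v) rho_v`, `a = sum_v pi(v) a_v`. The conditional
#' fixation time is by default the fixation-weighted mixture
#' `tau = sum_v pi(v) rho_v tau_v / sum_v pi(v) rho_v` -- the expected
#' number of steps over trajectories that fix when the start vertex is
#' itself random -- since conditioning and averaging do not commute. The
#' plain mean `sum_v pi(v) tau_v` is available via `tau_aggregation`.
#'
#' @param sol A `fixation_solution` ([solve_fixation()]).
#' @param scheme Initialization scheme (see [init_distribution()]).
#' @param kernel Replacement kernel; required when `scheme` is
#'   `"temperature"`.
#' @param tau_aggregation `"fixation-weighted"` (default) or `"mean"`.
#' @param include_selfloops Passed to [temperature()].
#' @return List with `rho`, `cond_fix_time`, `absorb_time`, `n`, `r`,
#'   `scheme`.
#' @export
aggregate_solution <- function(sol, scheme = "uniform", kernel = NULL,
                               tau_aggregation = c("fixation-weighted",
                                                   "mean"),
                               include_selfloops = TRUE) {
  tau_aggregation <- match.arg(tau_aggregation)
  if (is.character(scheme) && scheme == "temperature" && is.null(kernel))
    stop("temperature initialization needs the kernel")
  pi_v <- init_distribution(scheme, kernel, include_selfloops)
  if (length(pi_v) != sol$n) stop("scheme and solution sizes differ")
  rho <- sum(pi_v * sol$rho)
  if (rho <= 0) stop("all starting vertices have zero fixation probability")
  tau <- if (tau_aggregation == "fixation-weighted")
    sum(pi_v * sol$rho * sol$cond_fix_time) / rho
  else sum(pi_v * sol$cond_fix_time)
  list(rho = rho,
       cond_fix_time = tau,
       absorb_time = sum(pi_v * sol$absorb_time),
       n = sol$n, r = sol$r,
       scheme = if (is.character(scheme)) scheme else "custom")
}

#' Effective rate of evolution
#'
#' Combines mutation supply and fixation dynamics into a single rate:
#' `t1 = 1/(N mu rho)` generations to produce a mutant destined to fix,
#' `t2 = tau/N` generations for it to fix once produced (`tau` in Moran
#' steps), and the effective rate is `1/(t1 + t2)` per generation. High
#' mutation rates are limited by fixation time, low ones by mutant supply.
#'
#' @param n Population size.
#' @param mu Mutation rate per individual per generation.
#' @param rho Fixation probability.
#' @param fix_time Conditional fixation time in Moran steps.
#' @return Effective rate (generations^-1); vectorized over arguments.
#' @export
effective_rate <- function(n, mu, rho, fix_time) {
  if (any(n <= 0) || any(mu <= 0) || any(rho <= 0) || any(fix_time <= 0))
    stop("all rate parameters must be positive")
  1 / (1 / (n * mu * rho) + fix_time / n)
}

#' Pareto front of probability-time tradeoff records
#'
#' Keeps the records not strictly dominated under (maximize fixation
#' probability, minimize conditional fixation time): a record dominates
#' another if it is at least as good in both coordinates and strictly
#' better in one. Differences within `tol` are treated as ties, and tied
#' records are all kept.
#'
#' @param records Data frame with columns named by `rho_col` and
#'   `time_col`.
#' @param rho_col,time_col Column names.
#' @param tol Tie tolerance.
#' @return The non-dominated subset of `records` (same columns).
#' @export
pareto_front <- function(records, rho_col = "rho",
                         time_col = "fix_time_steps", tol = 1e-12) {
  records[pareto_flags(records[[rho_col]], records[[time_col]], tol), ,
          drop = FALSE]
}

pareto_flags <- function(rho, time, tol = 1e-12) {
  m <- length(rho)
  if (m == 0L) return(logical(0))
  keep <- logical(m)
  for (i in seq_len(m)) {
    dominated <- any(
      rho >= rho[i] - tol & time <= time[i] + tol &
        (rho > rho[i] + tol | time < time[i] - tol))
    keep[i] <- !dominated
  }
  keep
}

#' Universal lower bound on the absorption time
#'
#' For any population structure, the expected absorption time of a single
#' mutant exceeds `(rho/r) * N * log(N)` Moran steps, where `rho` is the
#' aggregated fixation probability: gaining the k-th mutant requires one of
#' the k mutants to reproduce, which takes at least order `N/k` steps, and
#' the harmonic sum gives `N log N`. Consequently no amplifier (nor any
#' structure whose fixation probability stays bounded away from zero) can
#' beat the well-mixed absorption time asymptotically.
#'
#' @param rho Aggregated fixation probability in (0, 1].
#' @param r Mutant fitness (> 0).
#' @param n Population size (>= 2).
#' @return The bound, in Moran steps (natural log).
#' @export
absorption_lower_bound <- function(rho, r, n) {
  if (any(rho <= 0) || any(rho > 1) || any(r <= 0) || any(n < 2))
    stop("require rho in (0,1], r > 0, n >= 2")
  rho / r * n * log(n)
}
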