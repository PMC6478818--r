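#' Exact statistics of a one-dimensional birth-death chain
#'
#' Solves an absorbing birth-death chain on states `0..K` (absorbing at the
#' endpoints) with per-state up/down probabilities; the remaining mass is a
#' hold probability, so expected times count every step including holds.
#' The three tridiagonal linear systems (fixation probability, absorption
#' time, fixation-conditioned time) are solved by sparse LU factorization,
#' which is exact up to rounding and avoids the catastrophic cancellation
#' that the classical product-sum formulas suffer for large `r^k` factors.
#'
#' @param up,down Numeric vectors of length `K - 1`: transition
#'   probabilities from state `k` to `k + 1` resp. `k - 1`, for
#'   `k = 1..K-1`.
#' @return Data frame with one row per interior state `k`: `rho`,
#'   `absorb_time`, `cond_fix_time`.
#' @export
bd_chain_stats <- function(up, down) {
  K <- length(up) + 1L
  if (length(down) != K - 1L) stop("up and down must have equal length")
  if (any(up < 0) || any(down < 0) || any(up + down > 1 + 1e-12))
    stop("invalid transition probabilities")
  k <- seq_len(K - 1L)
  ii <- c(k, k[-(K - 1L)], k[-1L])
  jj <- c(k, k[-(K - 1L)] + 1L, k[-1L] - 1L)
  xx <- c(up + down, -up[-(K - 1L)], -down[-1L])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(K - 1L, K - 1L))
  rhs_rho <- numeric(K - 1L); rhs_rho[K - 1L] <- up[K - 1L]
  sol <- as.matrix(Matrix::solve(A, cbind(rhs_rho, rep(1, K - 1L))))
  rho <- sol[, 1]
  z <- as.numeric(Matrix::solve(A, rho))
  data.frame(k = k, rho = rho, absorb_time = sol[, 2],
             cond_fix_time = z / rho)
}

#' Fixation statistics for the well-mixed population (complete graph)
#'
#' Lumps the complete graph by mutant count into a birth-death chain and
#' solves it exactly. The fixation probability agrees with the closed form
#' `(1 - 1/r)/(1 - 1/r^N)` (and `1/N` for the neutral case `r = 1`, which
#' needs no special handling in the linear-system formulation); times are
#' exact values in Moran steps, whose large-N behavior is
#' `[(r+1)/r] N log N` (absorption) and `[(r+1)/(r-1)] N log N` (fixation)
#' for `r > 1`, and `(N-1)^2` fixation time for `r = 1`.
#'
#' @param n Population size (>= 2); exact solves are practical to
#'   `n ~ 10^4`.
#' @param r Mutant relative fitness (> 0).
#' @return List with `rho`, `absorb_time`, `cond_fix_time` (single-mutant
#'   start; all vertices are equivalent, so every initialization scheme
#'   coincides), plus `n`, `r`.
#' @export
complete_graph_stats <- function(n, r) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (r <= 0) stop("r must be positive")
  k <- seq_len(n - 1L)
  F <- n + (r - 1) * k
  up <- (r * k / F) * (n - k) / (n - 1)
  down <- ((n - k) / F) * k / (n - 1)
  st <- bd_chain_stats(up, down)
  list(rho = st$rho[1], absorb_time = st$absorb_time[1],
       cond_fix_time = st$cond_fix_time[1], n = n, r = r,
       scheme = "any", family = "complete")
}

#' Fixation statistics for (weighted) complete bipartite graphs
#'
#' Within each part all vertices are automorphic, so the full `2^N`
#' configuration chain lumps exactly onto the two-dimensional chain of
#' mutant counts `(i, j)` (large part, small part), with
#' `(m+1)(s+1)` states instead of `2^(m+s)`. The chain is solved by sparse
#' LU factorization, giving exact fixation probability, absorption time,
#' and conditional fixation time (all in Moran steps, holds included) for
#' populations in the thousands. The star graph is the special case
#' `m = n - 1, s = 1, l = 0` ([star_stats()]).
#'
#' @param m,s Part sizes, `m >= s >= 1` (large part first).
#' @param selfloop_weight Self-loop weight `l` on each large-part vertex
#'   (0 for the unweighted balanced family).
#' @param r Mutant relative fitness.
#' @param init `"uniform"` or `"temperature"` initial-mutant placement.
#' @param tau_aggregation How to aggregate the conditional fixation time
#'   over starting parts (see [aggregate_solution()]).
#' @param temperature_selfloops Count self-loop weight in part
#'   temperatures (default) or exclude it.
#' @param count_holds If `TRUE` (default) times count every Moran step,
#'   including no-change steps (same-type replacements and self-loop
#'   self-replacements); if `FALSE`, times count only type-changing
#'   events (the embedded jump chain). Fixation probabilities are
#'   identical under both conventions.
#' @param max_states Refuse chains larger than this many states.
#' @return List with aggregated `rho`, `cond_fix_time`, `absorb_time`,
#'   the per-start-part table `per_start`, and metadata `n`, `r`,
#'   `scheme`.
#' @export
bipartite_stats <- function(m, s, selfloop_weight = 0, r = 1.1,
                            init = c("uniform", "temperature"),
                            tau_aggregation = c("fixation-weighted", "mean"),
                            temperature_selfloops = TRUE,
                            count_holds = TRUE,
                            max_states = 5e6) {
  init <- match.arg(init)
  tau_aggregation <- match.arg(tau_aggregation)
  m <- as.integer(m); s <- as.integer(s)
  if (s > m || s < 1L) stop("require m >= s >= 1")
  if (selfloop_weight < 0) stop("selfloop_weight must be nonnegative")
  if (r <= 0) stop("r must be positive")
  nst <- (m + 1) * (s + 1)
  if (nst > max_states) stop("lumped chain too large (", nst, " states)")
  l <- selfloop_weight
  n <- m + s

  grid <- expand.grid(j = 0:s, i = 0:m)  # id = i*(s+1) + j + 1
  i <- grid$i; j <- grid$j
  id <- function(i, j) i * (s + 1L) + j + 1L
  F <- n + (r - 1) * (i + j)
  up_i <- (r * j / F) * (m - i) / m          # small mutant -> large resident
  dn_i <- ((s - j) / F) * i / m              # small resident -> large mutant
  up_j <- (r * i / F) * (s - j) / (l + s)    # large mutant -> small resident
  dn_j <- ((m - i) / F) * j / (l + s)        # large resident -> small mutant

  if (!count_holds) {
    # embedded jump chain: condition each step on a type change
    move <- up_i + dn_i + up_j + dn_j
    move[move == 0] <- 1  # absorbing states, never used
    up_i <- up_i / move; dn_i <- dn_i / move
    up_j <- up_j / move; dn_j <- dn_j / move
  }

  from <- id(i, j)
  tri_i <- c(from[up_i > 0], from[dn_i > 0], from[up_j > 0], from[dn_j > 0])
  tri_j <- c(id(i + 1L, j)[up_i > 0], id(i - 1L, j)[dn_i > 0],
             id(i, j + 1L)[up_j > 0], id(i, j - 1L)[dn_j > 0])
  tri_x <- c(up_i[up_i > 0], dn_i[dn_i > 0], up_j[up_j > 0], dn_j[dn_j > 0])
  hold <- 1 - (up_i + dn_i + up_j + dn_j)
  keep_hold <- hold > 0
  P <- Matrix::sparseMatrix(
    i = c(tri_i, from[keep_hold]), j = c(tri_j, from[keep_hold]),
    x = c(tri_x, hold[keep_hold]), dims = c(nst, nst))

  full <- id(m, s)
  transient <- setdiff(seq_len(nst), c(1L, full))
  A <- Matrix::Diagonal(length(transient)) - P[transient, transient]
  sol <- as.matrix(Matrix::solve(
    A, cbind(as.numeric(P[transient, full]), rep(1, length(transient)))))
  rho_t <- sol[, 1]; a_t <- sol[, 2]
  z_t <- as.numeric(Matrix::solve(A, rho_t))

  starts <- match(c(id(1L, 0L), id(0L, 1L)), transient)  # (1,0), (0,1)
  per <- data.frame(
    part = c("large", "small"),
    rho = rho_t[starts], absorb_time = a_t[starts],
    cond_fix_time = z_t[starts] / rho_t[starts])

  w <- bipartite_part_weights(m, s, l, init, temperature_selfloops)
  rho <- sum(w * per$rho)
  tau <- if (tau_aggregation == "fixation-weighted")
    sum(w * per$rho * per$cond_fix_time) / rho
  else sum(w * per$cond_fix_time)
  list(rho = rho, cond_fix_time = tau,
       absorb_time = sum(w * per$absorb_time),
       per_start = per, n = n, r = r, scheme = init,
       family = sprintf("bipartite(m=%d,s=%d,l=%g)", m, s, l))
}

# Probability that the initial mutant lands in the large/small part.
bipartite_part_weights <- function(m, s, l, init, selfloops = TRUE) {
  if (init == "uniform") {
    w <- c(m, s)
  } else {
    # summed temperatures: large part receives its own self-loops (if
    # counted) plus the small part's offspring; small part receives the
    # large part's cross-placed offspring.
    w_large <- if (selfloops) m * l / (l + s) + s else s
    w_small <- m * s / (l + s)
    w <- c(w_large, w_small)
  }
  w / sum(w)
}

#' Fixation statistics for the star graph via the lumped bipartite chain
#'
#' The star with `n - 1` leaves is the complete bipartite graph with parts
#' `(n - 1, 1)` and no self-loops; its `(leaf count, center)` chain has
#' `2n` states and solves exactly for populations in the thousands. For
#' `r > 1` and large `n` the uniform-initialization fixation probability
#' tends to `1 - 1/r^2` -- the classic amplification of the star -- while
#' both times grow like `N^2 log N`.
#'
#' @param n Population size (>= 3).
#' @inheritParams bipartite_stats
#' @return As [bipartite_stats()].
#' @export
#' @examples
#' star_stats(1000, r = 1.1)$rho  # near 1 - 1/1.1^2
star_stats <- function(n, r, init = c("uniform", "temperature"),
                       tau_aggregation = c("fixation-weighted", "mean")) {
  n <- as.integer(n)
  if (n < 3L) stop("star requires n >= 3")
  out <- bipartite_stats(n - 1L, 1L, 0, r, init = init,
                         tau_aggregation = tau_aggregation)
  out$family <- sprintf("star(n=%d)", n)
  out
}

#' Choose bipartite part sizes for a total population size
#'
#' The asymptotic definitions of the balanced/weighted bipartite families
#' use the large-part size as `N`; for finite-size comparisons at a fixed
#' total population (e.g. "graphs of size N = 100"), this helper scans the
#' large-part size `m` so that `m + round(m^(1-alpha))` is as close as
#' possible to the requested total (ties resolved towards the larger `m`).
#'
#' @param n_total Target total population size.
#' @param alpha Imbalance exponent in (0, 1].
#' @return List with `m`, `s`.
#' @export
bipartite_parts_for_total <- function(n_total, alpha) {
  m_grid <- seq_len(n_total)
  tot <- m_grid + pmax(1L, as.integer(round(m_grid^(1 - alpha))))
  ok <- which(m_grid >= pmax(1L, as.integer(round(m_grid^(1 - alpha)))))
  best <- ok[order(abs(tot[ok] - n_total), -m_grid[ok])][1]
  list(m = m_grid[best],
       s = pmax(1L, as.integer(round(m_grid[best]^(1 - alpha)))))
}
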