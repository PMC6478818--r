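#' One-step transition distribution of the Moran process
#'
#' Given the current mutant configuration, enumerates every reachable next
#' configuration with its probability: a reproducer `u` is picked with
#' probability `f(u)/F` (fitness `r` for mutants, 1 for residents, `F` the
#' population total), its offspring lands on `v` with kernel probability
#' `w(u, v)`, and `v` adopts `u`'s type. Same-type replacements (including
#' self-loops) leave the configuration unchanged and appear as a
#' self-transition.
#'
#' @param kernel Row-stochastic replacement kernel
#'   ([replacement_kernel()]).
#' @param r Mutant relative fitness (> 0).
#' @param config Integer vector of vertices currently occupied by mutants
#'   (1-based); must be neither empty nor the full vertex set.
#' @return A data frame with list-column `config` (next configurations as
#'   sorted integer vectors) and `prob`; probabilities sum to 1.
#' @export
step_distribution <- function(kernel, r, config) {
  n <- nrow(kernel)
  config <- sort(unique(as.integer(config)))
  if (length(config) == 0L || length(config) == n)
    stop("configuration is absorbing (empty or full)")
  if (r <= 0) stop("r must be positive")
  is_mut <- logical(n); is_mut[config] <- TRUE
  k <- length(config)
  F <- n + (r - 1) * k
  acc <- new.env(parent = emptyenv())
  add <- function(cfg, p) {
    key <- paste0("c", paste(cfg, collapse = ","))
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  for (u in seq_len(n)) {
    pu <- (if (is_mut[u]) r else 1) / F
    for (v in which(kernel[u, ] > 0)) {
      nxt <- if (is_mut[u]) union(config, v) else setdiff(config, v)
      add(sort(nxt), pu * kernel[u, v])
    }
  }
  keys <- ls(acc)
  cfgs <- lapply(keys, function(k_) {
    body <- substring(k_, 2)
    if (nchar(body) == 0L) integer(0)
    else as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
  })
  data.frame(
    config = I(cfgs),
    prob = vapply(keys, function(k_) acc[[k_]], numeric(1)),
    row.names = NULL
  )
}

#' Exact fixation probabilities and times via the full configuration chain
#'
#' Solves the absorbing Markov chain over all `2^n` mutant configurations:
#' fixation probabilities satisfy `rho_S = sum_S' P(S, S') rho_S'` with
#' `rho = 1` at the all-mutant state and 0 at the empty state; absorption
#' times satisfy `a_S = 1 + sum P a_S'` with `a = 0` at the absorbing
#' states; conditional fixation times are obtained from the auxiliary
#' system `z_S = rho_S + sum P z_S'` with `tau_S = z_S / rho_S` (and the
#' mirrored system for the extinction-conditioned time). Self-transitions
#' are retained, so all times count every Moran step, including same-type
#' replacements -- essential for graphs with heavy self-loops.
#'
#' @param kernel Row-stochastic replacement kernel.
#' @param r Mutant relative fitness (> 0).
#' @param max_vertices State-space cap: refuse `n` above this (default 14,
#'   i.e. at most 16,384 configurations); use the lumped solvers or the
#'   simulator beyond it.
#' @return A `fixation_solution`: list with per-starting-vertex vectors
#'   `rho`, `absorb_time`, `cond_fix_time`, `ext_time` (extinction-
#'   conditioned absorption time), plus `n` and `r`. Times are in Moran
#'   steps.
#' @export
#' @examples
#' sol <- solve_fixation(replacement_kernel(make_complete(5)), r = 1.1)
#' mean(sol$rho)   # matches (1 - 1/r)/(1 - 1/r^5)
solve_fixation <- function(kernel, r, max_vertices = 14L) {
  n <- nrow(kernel)
  if (n > max_vertices)
    stop("n = ", n, " exceeds the full-state cap (", max_vertices,
         "); use the lumped solvers or the simulator")
  if (r <= 0) stop("r must be positive")
  rs <- rowSums(kernel)
  if (any(abs(rs - 1) > 1e-9)) stop("kernel rows must sum to 1")

  tri <- moran_transition_triplets(kernel, r)
  nstates <- as.integer(tri$nstates)
  full <- nstates  # state index of the all-mutant mask
  transient <- setdiff(seq_len(nstates), c(1L, full))
  P <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(nstates, nstates))
  A <- Matrix::Diagonal(length(transient)) - P[transient, transient]
  rhs1 <- cbind(as.numeric(P[transient, full]), rep(1, length(transient)))
  sol1 <- as.matrix(Matrix::solve(A, rhs1))
  rho_t <- sol1[, 1]; a_t <- sol1[, 2]
  resid <- max(abs(A %*% sol1 - rhs1))
  if (!is.finite(resid) || resid > 1e-9)
    stop("linear solve residual too large (", signif(resid, 3),
         "); chain may be structurally singular")
  sol2 <- as.matrix(Matrix::solve(A, cbind(rho_t, 1 - rho_t)))
  z_t <- sol2[, 1]; zext_t <- sol2[, 2]

  # single-mutant slices: mask 2^(v-1) -> transient position
  pos <- match(2^(seq_len(n) - 1) + 1, transient)
  rho <- rho_t[pos]
  structure(list(
    n = n, r = r,
    rho = rho,
    absorb_time = a_t[pos],
    cond_fix_time = z_t[pos] / rho,
    ext_time = zext_t[pos] / (1 - rho)
  ), class = "fixation_solution")
}

#' @export
print.fixation_solution <- function(x, ...) {
  cat(sprintf("<fixation_solution> n = %d, r = %g\n", x$n, x$r))
  print(data.frame(vertex = seq_len(x$n), rho = x$rho,
                   absorb_time = x$absorb_time,
                   cond_fix_time = x$cond_fix_time))
  invisible(x)
}

#' Classify a structure against the well-mixed population
#'
#' Compares aggregated fixation probability and conditional fixation time
#' of a graph with those of the complete graph of the same size and fitness:
#' amplifiers raise the fixation probability, suppressors lower it;
#' accelerators shorten the conditional fixation time, decelerators
#' lengthen it. Differences within `tol` count as ties (no flag).
#'
#' @param agg_g,agg_k Aggregated summaries (as returned by
#'   [aggregate_solution()] or the lumped solvers) for the graph and for
#'   the complete graph; must share `n` and `r`.
#' @param tol Tie tolerance.
#' @return Named logical vector with elements `amplifier`, `suppressor`,
#'   `accelerator`, `decelerator`.
#' @export
classify_vs_complete <- function(agg_g, agg_k, tol = 1e-10) {
  if (!is.null(agg_g$n) && !is.null(agg_k$n) && agg_g$n != agg_k$n)
    stop("population sizes differ")
  if (!is.null(agg_g$r) && !is.null(agg_k$r) && agg_g$r != agg_k$r)
    stop("fitness values differ")
  drho <- agg_g$rho - agg_k$rho
  dtau <- agg_g$cond_fix_time - agg_k$cond_fix_time
  c(amplifier = drho > tol,
    suppressor = drho < -tol,
    accelerator = dtau < -tol,
    decelerator = dtau > tol)
}
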