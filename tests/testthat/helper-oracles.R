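# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers so that agreement is a genuine cross-check.

# Closed-form fixation probability of a single mutant in the well-mixed
# population of size n.
moran_rho_closed_form <- function(n, r) {
  if (r == 1) return(1 / n)
  (1 - 1 / r) / (1 - 1 / r^n)
}

# Brute-force enumeration of connected unlabeled graphs on n vertices by
# scanning all labeled graphs and rejecting isomorphs with igraph's VF2
# test (feasible for n <= 5). Independent of the package's canonical
# augmentation.
brute_force_connected_count <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  reps <- list()
  for (code in 0:(2^m - 1)) {
    keep <- bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) != 0L
    if (!any(keep)) next
    ig <- igraph::graph_from_edgelist(t(pairs[, keep, drop = FALSE]),
                                      directed = FALSE)
    if (igraph::vcount(ig) < n)
      ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    if (!igraph::is_connected(ig)) next
    if (!any(vapply(reps, function(h)
      igraph::isomorphic(ig, h, method = "vf2"), logical(1))))
      reps[[length(reps) + 1]] <- ig
  }
  length(reps)
}

# Full-state Moran transition matrix built from first principles with
# plain nested loops (independent of the package's triplet builder).
brute_force_transition_matrix <- function(W, r) {
  n <- nrow(W)
  ns <- 2^n
  P <- matrix(0, ns, ns)
  for (mask in 0:(ns - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L)
    k <- sum(bits)
    if (k == 0 || k == n) { P[mask + 1, mask + 1] <- 1; next }
    F <- n + (r - 1) * k
    for (u in 1:n) {
      pu <- (if (bits[u] == 1) r else 1) / F
      for (v in 1:n) {
        if (W[u, v] <= 0) next
        nxt <- if (bits[u] == 1) bitwOr(mask, bitwShiftL(1L, v - 1))
               else bitwAnd(mask, bitwNot(bitwShiftL(1L, v - 1)))
        P[mask + 1, nxt + 1] <- P[mask + 1, nxt + 1] + pu * W[u, v]
      }
    }
  }
  P
}

# Truncated trajectory summation of the fixation-weighted conditional
# fixation time under a random start: iterate the distribution forward,
# accumulating the probability of first absorption at the full state at
# each step. Exact up to the geometric tail, which is driven below
# machine precision.
brute_force_cond_fix_time <- function(W, r, start_weights,
                                      max_steps = 20000) {
  n <- nrow(W)
  P <- brute_force_transition_matrix(W, r)
  full <- 2^n
  p <- numeric(2^n)
  for (v in 1:n) p[2^(v - 1) + 1] <- start_weights[v]
  num <- 0; den <- 0
  for (t in 1:max_steps) {
    arriving <- as.numeric(p[-c(1, full)] %*% P[-c(1, full), full])
    num <- num + t * arriving
    den <- den + arriving
    p[c(1, full)] <- 0
    p <- as.numeric(p %*% P)
    p[c(1, full)] <- 0  # absorbed mass accounted above
    if (sum(p) < 1e-16) break
  }
  list(tau = num / den, rho = den, tail = sum(p))
}

# Seeded random connected graph for property tests.
random_connected_graph <- function(n, seed) {
  make_erdos_renyi(n, p = min(1, 2.5 / n + 0.15), seed = seed)
}
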