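#' Weighted population-structure graphs
#'
#' A `weighted_graph` represents a population structure for the Moran
#' birth-death process: each of the `n` vertices holds one individual, and a
#' positive edge weight `w(u, v)` expresses the propensity of a reproducing
#' individual at `u` to place its offspring at `v`. Self-loops are allowed
#' (an offspring may replace its own parent). Vertices are indexed `1..n`.
#'
#' @param n Number of vertices (population size), a positive integer.
#' @param edges A data frame with columns `from`, `to`, `weight`
#'   (positive). For undirected graphs each edge is stored once; the
#'   replacement kernel expands it in both directions.
#' @param directed Logical; if `TRUE`, edges are one-way.
#' @param name Optional label for the graph (used in result tables).
#' @param validate Logical; verify invariants (positive weights,
#'   connectivity of the non-self-loop skeleton).
#'
#' @return An object of class `weighted_graph`: a list with elements `n`,
#'   `edges`, `directed`, `name`.
#' @export
#' @examples
#' g <- make_star(5)
#' replacement_kernel(g)
weighted_graph <- function(n, edges, directed = FALSE, name = NULL,
                           validate = TRUE) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n` must be a single positive integer")
  edges <- as.data.frame(edges)
  if (!all(c("from", "to", "weight") %in% names(edges)))
    stop("`edges` must have columns from, to, weight")
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  edges$weight <- as.numeric(edges$weight)
  g <- structure(
    list(n = n, edges = edges, directed = isTRUE(directed),
         name = if (is.null(name)) sprintf("graph_n%d", n) else name),
    class = "weighted_graph"
  )
  if (validate) validate_weighted_graph(g)
  g
}

validate_weighted_graph <- function(g) {
  e <- g$edges
  if (nrow(e) > 0) {
    if (any(e$from < 1L | e$from > g$n | e$to < 1L | e$to > g$n))
      stop("edge endpoints out of range 1..n")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      stop("all edge weights must be positive and finite ",
           "(omit zero-weight edges)")
  }
  skel <- e[e$from != e$to, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    skel[, c("from", "to")],
    directed = g$directed,
    vertices = data.frame(name = seq_len(g$n))
  )
  mode <- if (g$directed) "strong" else "weak"
  if (g$n > 1L && !igraph::is_connected(ig, mode = mode))
    stop("graph (excluding self-loops) must be ",
         if (g$directed) "strongly connected" else "connected")
  invisible(g)
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph '%s'> %d vertices, %d edges (%s)%s\n",
              x$name, x$n, nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              if (any(x$edges$from == x$edges$to)) ", with self-loops" else ""))
  invisible(x)
}

#' Replacement kernel of a population structure
#'
#' Normalizes the edge weights of a [weighted_graph()] into the
#' offspring-placement distribution of the Moran process: `w(u, v)` is the
#' probability that an individual reproducing at vertex `u` places its
#' offspring at vertex `v`. Rows are normalized per source vertex, so each
#' row sums to one. Undirected edges contribute in both directions.
#'
#' @param g A [weighted_graph()].
#' @return An `n x n` row-stochastic dense matrix.
#' @export
replacement_kernel <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- g$n
  W <- matrix(0, n, n)
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    W[e$from[i], e$to[i]] <- W[e$from[i], e$to[i]] + e$weight[i]
    if (!g$directed && e$from[i] != e$to[i])
      W[e$to[i], e$from[i]] <- W[e$to[i], e$from[i]] + e$weight[i]
  }
  rs <- rowSums(W)
  if (any(rs == 0)) stop("every vertex needs at least one outgoing edge")
  W / rs
}

undirected_edges <- function(from, to, weight = 1) {
  data.frame(from = as.integer(from), to = as.integer(to),
             weight = as.numeric(weight))
}

#' Complete graph (well-mixed population)
#'
#' In the well-mixed population every offspring is equally likely to replace
#' any of the other `n - 1` individuals, so the kernel has `w(u, v) =
#' 1/(n-1)` for all `u != v`.
#'
#' @param n Population size, at least 2.
#' @return A [weighted_graph()].
#' @export
make_complete <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("complete graph requires n >= 2")
  idx <- utils::combn(n, 2L)
  weighted_graph(n, undirected_edges(idx[1, ], idx[2, ]),
                 name = sprintf("K_%d", n), validate = FALSE)
}

#' Star graph
#'
#' One central vertex (vertex 1 by convention) connected to `n - 1` leaves.
#' The classic amplifier of selection: a leaf's offspring always lands on
#' the center, the center's offspring lands on a uniformly random leaf.
#'
#' @param n Population size, at least 3.
#' @return A [weighted_graph()].
#' @export
make_star <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("star graph requires n >= 3")
  weighted_graph(n, undirected_edges(1L, 2:n),
                 name = sprintf("S_%d", n), validate = FALSE)
}

#' Complete bipartite graph, optionally with self-loops on the large part
#'
#' Vertices `1..m` form the large part and `m+1..m+s` the small part; every
#' cross pair is joined by a unit-weight edge and, if `selfloop_weight > 0`,
#' each large-part vertex additionally carries a self-loop of that weight.
#' With self-loop weight `l`, a large-part vertex's offspring stays home
#' with probability `l/(l+s)` and lands on any given small-part vertex with
#' probability `1/(l+s)`; a small-part vertex's offspring lands on any given
#' large-part vertex with probability `1/m`.
#'
#' @param m Size of the large part (`m >= s`).
#' @param s Size of the small part.
#' @param selfloop_weight Nonnegative weight of the self-loop attached to
#'   each large-part vertex (0 = none).
#' @return A [weighted_graph()].
#' @export
make_complete_bipartite <- function(m, s, selfloop_weight = 0) {
  m <- as.integer(m); s <- as.integer(s)
  if (s > m) stop("parts swapped: require m >= s")
  if (m < 1L || s < 1L || m + s < 3L) stop("require m >= s >= 1 and m + s >= 3")
  if (!is.finite(selfloop_weight) || selfloop_weight < 0)
    stop("selfloop_weight must be nonnegative")
  cross <- expand.grid(from = seq_len(m), to = m + seq_len(s))
  edges <- undirected_edges(cross$from, cross$to)
  if (selfloop_weight > 0)
    edges <- rbind(edges, undirected_edges(seq_len(m), seq_len(m),
                                           selfloop_weight))
  weighted_graph(m + s, edges,
                 name = sprintf("B(%d,%d,l=%g)", m, s, selfloop_weight),
                 validate = FALSE)
}

small_part_size <- function(n_large, alpha) {
  max(1L, as.integer(round(n_large^(1 - alpha))))
}

#' alpha-Balanced bipartite graph
#'
#' A complete bipartite graph with parts of sizes `n_large` and
#' `round(n_large^(1-alpha))`. For large populations this family attains the
#' star graph's fixation probability (tending to `1 - 1/r^2`) under uniform
#' initialization while keeping the conditional fixation time of order
#' `N^(1+alpha) log N`, far below the star's `N^2 log N`.
#'
#' @param n_large Size of the large part, at least 4.
#' @param alpha Imbalance exponent in (0, 1): small `alpha` means nearly
#'   equal parts, large `alpha` a star-like imbalance.
#' @return A [weighted_graph()].
#' @export
make_balanced_bipartite <- function(n_large, alpha) {
  if (n_large < 4L) stop("require n_large >= 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  s <- small_part_size(n_large, alpha)
  g <- make_complete_bipartite(n_large, s, 0)
  g$name <- sprintf("B_{%d,%g}", n_large, alpha)
  g
}

#' alpha-Weighted bipartite graph
#'
#' The self-loop version of [make_balanced_bipartite()]: each large-part
#' vertex carries a self-loop of weight `n_large^(1-alpha/2) -
#' n_large^(1-alpha)` (exact real value, not rounded), so its offspring
#' replaces the parent most of the time and migrates to the small part only
#' with probability about `n_large^(-alpha/2)`. Under temperature
#' initialization this family amplifies to `1 - 1/r^2` in the large-N limit
#' where unweighted graphs cannot.
#'
#' @inheritParams make_balanced_bipartite
#' @param alpha Imbalance exponent in (0, 1].
#' @return A [weighted_graph()].
#' @export
make_weighted_bipartite <- function(n_large, alpha) {
  if (n_large < 4L) stop("require n_large >= 4")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  s <- small_part_size(n_large, alpha)
  loop <- n_large^(1 - alpha / 2) - n_large^(1 - alpha)
  if (loop <= 0) stop("self-loop weight must be positive")
  g <- make_complete_bipartite(n_large, s, loop)
  g$name <- sprintf("W_{%d,%g}", n_large, alpha)
  g
}

#' Cycle graph
#'
#' @param n Population size, at least 3.
#' @return A [weighted_graph()].
#' @export
make_cycle <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("cycle requires n >= 3")
  weighted_graph(n, undirected_edges(seq_len(n), c(2:n, 1L)),
                 name = sprintf("C_%d", n), validate = FALSE)
}

#' Uniform random labeled tree
#'
#' Samples uniformly over the `n^(n-2)` labeled trees via a random Pruefer
#' sequence.
#'
#' @param n Number of vertices, at least 3.
#' @param seed Integer seed; same seed gives the identical tree.
#' @return A [weighted_graph()].
#' @export
make_random_tree <- function(n, seed) {
  n <- as.integer(n)
  if (n < 3L) stop("require n >= 3")
  edges <- with_graph_seed(seed, {
    prufer <- sample.int(n, n - 2L, replace = TRUE)
    degree <- rep(1L, n)
    for (p in prufer) degree[p] <- degree[p] + 1L
    from <- integer(n - 1L); to <- integer(n - 1L)
    ptr <- 1L
    for (i in seq_along(prufer)) {
      leaf <- which(degree == 1L)[1L]
      from[i] <- leaf; to[i] <- prufer[i]
      degree[leaf] <- 0L
      degree[prufer[i]] <- degree[prufer[i]] - 1L
    }
    last <- which(degree == 1L)
    from[n - 1L] <- last[1L]; to[n - 1L] <- last[2L]
    undirected_edges(from, to)
  })
  weighted_graph(n, edges, name = sprintf("tree_%d_seed%d", n, seed))
}

#' Random connected Erdos-Renyi graph
#'
#' G(n, p) conditioned on connectivity by rejection sampling: graphs are
#' redrawn until connected, up to `max_retries` attempts.
#'
#' @param n Number of vertices, at least 3.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param max_retries Rejection-sampling cap before giving up.
#' @return A [weighted_graph()].
#' @export
make_erdos_renyi <- function(n, p, seed, max_retries = 10000L) {
  n <- as.integer(n)
  if (n < 3L) stop("require n >= 3")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  pairs <- utils::combn(n, 2L)
  with_graph_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      keep <- stats::runif(ncol(pairs)) < p
      if (!any(keep)) next
      edges <- undirected_edges(pairs[1, keep], pairs[2, keep])
      g <- tryCatch(
        weighted_graph(n, edges, name = sprintf("ER_%d_p%g_seed%d", n, p, seed)),
        error = function(e) NULL
      )
      if (!is.null(g)) return(g)
    }
    stop("could not generate a connected G(n, p) sample after ",
         max_retries, " attempts")
  })
}

add_random_edges <- function(g, k_extra, seed) {
  if (k_extra == 0L) return(g)
  pairs <- utils::combn(g$n, 2L)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  present <- key(g$edges$from, g$edges$to)
  free <- which(!(key(pairs[1, ], pairs[2, ]) %in% present))
  if (length(free) < k_extra)
    stop("not enough absent edges to add ", k_extra)
  pick <- with_graph_seed(seed, free[sample.int(length(free), k_extra)])
  g$edges <- rbind(g$edges,
                   undirected_edges(pairs[1, pick], pairs[2, pick]))
  g
}

#' Star or cycle with extra random edges
#'
#' Adds `k_extra` distinct uniformly random absent edges to a star or cycle
#' backbone; used as mildly perturbed reference families in tradeoff scans.
#'
#' @param n Number of vertices.
#' @param k_extra Number of extra edges (0 returns the plain backbone).
#' @param seed Integer seed.
#' @return A [weighted_graph()].
#' @export
make_star_plus_edges <- function(n, k_extra, seed) {
  g <- add_random_edges(make_star(n), as.integer(k_extra), seed)
  g$name <- sprintf("star+%d_%d_seed%d", k_extra, n, seed)
  g
}

#' @rdname make_star_plus_edges
#' @export
make_cycle_plus_edges <- function(n, k_extra, seed) {
  g <- add_random_edges(make_cycle(n), as.integer(k_extra), seed)
  g$name <- sprintf("cycle+%d_%d_seed%d", k_extra, n, seed)
  g
}

# Run expr under a temporary RNG state so graph generation is reproducible
# without disturbing the caller's RNG.
with_graph_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Convert between weighted_graph and igraph objects
#'
#' @param g A [weighted_graph()].
#' @return An [igraph::graph] with edge attribute `weight`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  igraph::graph_from_data_frame(
    g$edges, directed = g$directed,
    vertices = data.frame(name = seq_len(g$n)))
}
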