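#' Enumerate all connected graphs of small size
#'
#' Produces exactly one representative per isomorphism class of connected
#' simple undirected unweighted graphs on `n` vertices, in a deterministic
#' order (lexicographically sorted canonical upper-triangular adjacency
#' encoding). Built by canonical augmentation: every connected graph on `k`
#' vertices arises from a connected graph on `k - 1` vertices by attaching a
#' new vertex to a nonempty subset (every connected graph has a non-cut
#' vertex), so levels are grown from a single vertex, canonicalized, and
#' deduplicated. Canonical labellings come from igraph's BLISS backend.
#'
#' Results are cached per `n` within the session, so repeated calls (e.g.
#' a census check followed by a sweep) pay the cost once.
#'
#' @param n Number of vertices; the intended range is 3..8 (11,117 classes
#'   at n = 8). Larger n is permitted but warned about, as the class count
#'   grows superexponentially.
#' @param as Output form: `"graph"` for a list of [weighted_graph()]s or
#'   `"graph6"` for a character vector of graph6 strings.
#' @return A list of [weighted_graph()]s (or a character vector).
#' @seealso [count_connected_graphs()] for the analytic census.
#' @export
enumerate_connected_graphs <- function(n, as = c("graph", "graph6")) {
  as <- match.arg(as)
  n <- as.integer(n)
  if (n < 1L) stop("n must be positive")
  if (n > 8L)
    warning("enumeration beyond n = 8 is expensive (", n, " requested)")
  mats <- enumerate_adjacency(n)
  if (as == "graph6") return(vapply(mats, adjacency_to_graph6, character(1)))
  lapply(seq_along(mats), function(i) {
    adjacency_to_graph(mats[[i]], name = sprintf("enum_n%d_%d", n, i))
  })
}

the_cache <- new.env(parent = emptyenv())

enumerate_adjacency <- function(n) {
  key <- sprintf("enum%d", n)
  if (!is.null(the_cache[[key]])) return(the_cache[[key]])
  level <- list(matrix(0L, 1L, 1L))
  if (n > 1L) {
    for (k in 2:n) {
      seen <- new.env(parent = emptyenv(), size = 4L * length(level))
      subsets <- seq_len(2L^(k - 1L) - 1L)
      for (A in level) {
        B <- matrix(0L, k, k)
        B[seq_len(k - 1L), seq_len(k - 1L)] <- A
        for (s in subsets) {
          nbr <- which(bitwAnd(s, bitwShiftL(1L, 0:(k - 2L))) != 0L)
          B[k, ] <- 0L; B[, k] <- 0L
          B[k, nbr] <- 1L; B[nbr, k] <- 1L
          cf <- canonical_adjacency(B)
          ck <- paste(cf[upper.tri(cf)], collapse = "")
          if (is.null(seen[[ck]])) seen[[ck]] <- cf
        }
      }
      keys <- sort(ls(seen))
      level <- lapply(keys, function(kk) seen[[kk]])
    }
  }
  the_cache[[key]] <- level
  level
}

canonical_adjacency <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  p <- igraph::canonical_permutation(g)$labeling
  inv <- order(p)
  A[inv, inv, drop = FALSE]
}

adjacency_to_graph <- function(A, name = NULL) {
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  weighted_graph(nrow(A),
                 undirected_edges(idx[, 1], idx[, 2]),
                 name = name, validate = FALSE)
}

#' Count connected graphs up to isomorphism
#'
#' Analytic census of isomorphism classes of connected simple undirected
#' graphs on `n` vertices: the number of all unlabeled graphs is computed by
#' Burnside's lemma over cycle types of the vertex permutation group (each
#' permutation fixes `2^c` graphs where `c` is its number of edge orbits),
#' and the connected count is then extracted with the inverse Euler
#' transform. Agrees with [enumerate_connected_graphs()] wherever both run.
#'
#' Counts are exact as long as they are below 2^53 (comfortably so for
#' n <= 13, the practical range).
#'
#' @param n Number of vertices.
#' @return The number of connected graphs on `n` vertices up to isomorphism.
#' @export
#' @examples
#' count_connected_graphs(8)  # 11117
count_connected_graphs <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be positive")
  a <- vapply(seq_len(n), count_all_graphs, numeric(1))  # a[k]: all graphs
  # inverse Euler transform: a -> connected counts c
  b <- numeric(n); cc <- numeric(n)
  for (m in seq_len(n)) {
    acc <- 0
    if (m > 1L) for (k in seq_len(m - 1L)) acc <- acc + b[k] * a[m - k]
    b[m] <- m * a[m] - acc
    divs <- which(m %% seq_len(m - 1L) == 0L)
    cc[m] <- (b[m] - sum(divs * cc[divs])) / m
  }
  cc[n]
}

# Unlabeled simple graphs on n vertices via the cycle index of the pair group.
count_all_graphs <- function(n) {
  total <- 0
  for (lam in integer_partitions(n)) {
    # edge orbits of a vertex permutation with cycle lengths lam
    c_edges <- sum(floor(lam / 2))
    if (length(lam) > 1L) {
      pr <- utils::combn(length(lam), 2L)
      c_edges <- c_edges + sum(mapply(gcd2, lam[pr[1, ]], lam[pr[2, ]]))
    }
    m <- table(lam)  # multiplicities of each cycle length
    sym <- prod(as.numeric(names(m))^as.numeric(m)) * prod(factorial(m))
    total <- total + 2^c_edges / sym
  }
  total
}

gcd2 <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }

integer_partitions <- function(n) {
  rec <- function(n, maxpart) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (p in seq_len(min(n, maxpart))) {
      for (tail in rec(n - p, p)) out[[length(out) + 1L]] <- c(p, tail)
    }
    out
  }
  rec(n, n)
}
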