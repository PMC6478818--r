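#' Read and write graphs in graph6 format
#'
#' graph6 is a compact ASCII encoding for simple undirected unweighted
#' graphs (here limited to n <= 62, one byte of size header): the
#' upper-triangular adjacency bits, taken column by column, are packed six
#' per printable character. Used to exchange enumeration output.
#'
#' @param g A [weighted_graph()] (undirected, unit weights, no self-loops).
#' @return `graph_to_graph6()`: a graph6 string. `graph6_to_graph()`: a
#'   [weighted_graph()].
#' @export
graph_to_graph6 <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (g$directed) stop("graph6 encodes undirected graphs only")
  if (any(g$edges$from == g$edges$to)) stop("graph6 does not allow self-loops")
  A <- matrix(0L, g$n, g$n)
  A[cbind(g$edges$from, g$edges$to)] <- 1L
  A[cbind(g$edges$to, g$edges$from)] <- 1L
  adjacency_to_graph6(A)
}

adjacency_to_graph6 <- function(A) {
  n <- nrow(A)
  if (n > 62L) stop("graph6 writer supports n <= 62")
  bits <- A[upper.tri(A)]  # column-major == graph6 bit order
  pad <- (6L - length(bits) %% 6L) %% 6L
  bits <- c(bits, integer(pad))
  vals <- vapply(seq_len(length(bits) / 6L), function(k) {
    sum(bits[(6L * (k - 1L) + 1L):(6L * k)] * c(32L, 16L, 8L, 4L, 2L, 1L))
  }, integer(1))
  rawToChar(as.raw(c(n + 63L, vals + 63L)))
}

#' @rdname graph_to_graph6
#' @param s A graph6 string.
#' @param name Optional graph label.
#' @export
graph6_to_graph <- function(s, name = NULL) {
  bytes <- as.integer(charToRaw(s)) - 63L
  n <- bytes[1L]
  if (n < 0L || n > 62L) stop("unsupported or malformed graph6 header")
  nbits <- n * (n - 1L) / 2L
  bits <- integer(0)
  for (v in bytes[-1L])
    bits <- c(bits, as.integer(bitwAnd(bitwShiftR(v, 5:0), 1L)))
  if (length(bits) < nbits) stop("truncated graph6 string")
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- bits[seq_len(nbits)]
  A <- A + t(A)
  adjacency_to_graph(A, name = if (is.null(name)) s else name)
}

#' Read and write weighted directed edge-list TSV files
#'
#' The on-disk format is a tab-separated table with header
#' `source`, `target`, `weight` and 0-based vertex ids; self-loops are
#' allowed and undirected graphs are stored with both directions explicit.
#' (In memory, [weighted_graph()] uses 1-based ids, the R convention.)
#'
#' @param g A [weighted_graph()].
#' @param path File path.
#' @export
write_graph_tsv <- function(g, path) {
  stopifnot(inherits(g, "weighted_graph"))
  e <- g$edges
  if (!g$directed) {
    rev <- e[e$from != e$to, c("to", "from", "weight")]
    names(rev) <- c("from", "to", "weight")
    e <- rbind(e, rev)
  }
  out <- data.frame(source = e$from - 1L, target = e$to - 1L,
                    weight = e$weight)
  out <- out[order(out$source, out$target), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param name Optional graph label.
#' @return `read_graph_tsv()` returns a directed [weighted_graph()] (a
#'   symmetric edge list yields a kernel identical to the undirected
#'   original).
#' @export
read_graph_tsv <- function(path, name = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("source", "target", "weight") %in% names(d)))
    stop("TSV must have header: source, target, weight")
  n <- max(d$source, d$target) + 1L
  weighted_graph(n,
                 data.frame(from = d$source + 1L, to = d$target + 1L,
                            weight = d$weight),
                 directed = TRUE,
                 name = if (is.null(name)) basename(path) else name)
}
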