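#' Probability-time tradeoff sweep over all small connected graphs
#'
#' Enumerates the connected graphs on `n` vertices (or takes a supplied
#' list), solves each one exactly, aggregates fixation probability and
#' conditional fixation time under the chosen initialization scheme, flags
#' amplifiers/suppressors and accelerators/decelerators relative to the
#' complete graph, and marks the Pareto front of (maximize rho, minimize
#' fixation time).
#'
#' A full sweep at `n = 8` covers 11,117 graphs; for quicker certification
#' of the sweep's extremal structure, `sample_size` draws a stratified
#' subsample (by edge count) that always retains the complete graph, the
#' star, and every regular graph.
#'
#' @param n Number of vertices (<= 8 by default practice).
#' @param r Mutant relative fitness.
#' @param scheme `"uniform"` or `"temperature"`.
#' @param graphs Optional list of [weighted_graph()]s to sweep instead of
#'   the full enumeration.
#' @param sample_size Optional stratified subsample size.
#' @param seed Seed for the subsample draw.
#' @param progress_every Print progress every this many graphs (0 = quiet).
#' @return Data frame of tradeoff records: `graph_id` (graph6), `n`, `r`,
#'   `scheme`, `n_edges`, `is_regular`, `rho`, `fix_time_steps`,
#'   `absorb_time_steps`, classification flags, `on_pareto_front`.
#' @export
run_sweep <- function(n, r = 1.1, scheme = c("uniform", "temperature"),
                      graphs = NULL, sample_size = NULL, seed = 1,
                      progress_every = 0) {
  scheme <- match.arg(scheme)
  if (is.null(graphs)) graphs <- enumerate_connected_graphs(n)
  degs <- lapply(graphs, function(g)
    tabulate(c(g$edges$from, g$edges$to), nbins = g$n))
  n_edges <- vapply(graphs, function(g) nrow(g$edges), numeric(1))
  regular <- vapply(degs, function(d) length(unique(d)) == 1L, logical(1))

  if (!is.null(sample_size) && sample_size < length(graphs)) {
    is_star <- n_edges == n - 1 &
      vapply(degs, function(d) max(d) == n - 1, logical(1))
    keep_always <- which(regular | is_star |
                           n_edges == n * (n - 1) / 2)
    pick <- with_graph_seed(seed, {
      rest <- setdiff(seq_along(graphs), keep_always)
      strata <- split(rest, n_edges[rest])
      per <- ceiling(sample_size / length(strata))
      unlist(lapply(strata, function(s) s[sample.int(length(s),
                                                     min(per, length(s)))]))
    })
    sel <- sort(union(keep_always, pick))
    graphs <- graphs[sel]
    n_edges <- n_edges[sel]; regular <- regular[sel]
  }

  agg_k <- aggregate_complete_reference(n, r, scheme)
  rows <- vector("list", length(graphs))
  for (idx in seq_along(graphs)) {
    g <- graphs[[idx]]
    W <- replacement_kernel(g)
    agg <- aggregate_solution(solve_fixation(W, r), scheme, kernel = W)
    fl <- classify_vs_complete(agg, agg_k)
    rows[[idx]] <- data.frame(
      graph_id = graph_to_graph6(g), n = g$n, r = r, scheme = scheme,
      n_edges = n_edges[idx], is_regular = regular[idx],
      rho = agg$rho, fix_time_steps = agg$cond_fix_time,
      absorb_time_steps = agg$absorb_time,
      is_amplifier = unname(fl["amplifier"]),
      is_suppressor = unname(fl["suppressor"]),
      is_accelerator = unname(fl["accelerator"]),
      is_decelerator = unname(fl["decelerator"]))
    if (progress_every > 0 && idx %% progress_every == 0)
      message(sprintf("solved %d/%d graphs", idx, length(graphs)))
  }
  out <- do.call(rbind, rows)
  out$on_pareto_front <- pareto_flags(out$rho, out$fix_time_steps)
  out
}

aggregate_complete_reference <- function(n, r, scheme) {
  Wk <- replacement_kernel(make_complete(n))
  aggregate_solution(solve_fixation(Wk, r), scheme, kernel = Wk)
}

#' Exact lumped statistics for a named reference structure
#'
#' Parses a structure token -- `"complete"`, `"star"`, `"balanced:<alpha>"`
#' or `"weighted:<alpha>"` -- and returns exact fixation statistics from
#' the matching lumped solver. `part_convention` controls whether `n`
#' denotes the total population (`"total"`, the default, appropriate for
#' fixed-size comparisons) or the large-part size (`"large-part"`, the
#' asymptotic convention in which the small part holds `n^(1-alpha)`
#' further vertices).
#'
#' @param structure Structure token.
#' @param n Population size (interpreted per `part_convention`).
#' @param r Mutant relative fitness.
#' @param scheme `"uniform"` or `"temperature"`.
#' @param part_convention `"total"` or `"large-part"`.
#' @return As [bipartite_stats()] / [complete_graph_stats()].
#' @export
lumped_structure_stats <- function(structure, n, r,
                                   scheme = c("uniform", "temperature"),
                                   part_convention = c("total",
                                                       "large-part")) {
  scheme <- match.arg(scheme)
  part_convention <- match.arg(part_convention)
  tok <- strsplit(structure, ":", fixed = TRUE)[[1]]
  kind <- tok[1]
  if (kind == "complete") return(complete_graph_stats(n, r))
  if (kind == "star") return(star_stats(n, r, init = scheme))
  if (!kind %in% c("balanced", "weighted") || length(tok) != 2L)
    stop("unknown structure token: ", structure)
  alpha <- as.numeric(tok[2])
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha out of range in token: ", structure)
  parts <- if (part_convention == "total")
    bipartite_parts_for_total(n, alpha)
  else list(m = as.integer(n), s = small_part_size(n, alpha))
  loop <- if (kind == "weighted")
    parts$m^(1 - alpha / 2) - parts$m^(1 - alpha) else 0
  bipartite_stats(parts$m, parts$s, loop, r, init = scheme)
}

#' Log-spaced mutation-rate grid
#'
#' @param from,to Grid endpoints (inclusive).
#' @param per_decade Points per factor-of-ten interval.
#' @return Numeric vector of mutation rates.
#' @export
mu_log_grid <- function(from, to, per_decade = 4) {
  10^seq(log10(from), log10(to),
         by = 1 / per_decade * sign(log10(to) - log10(from)))
}

#' Effective rate of evolution across structures and mutation rates
#'
#' For each reference structure, computes exact (lumped) fixation
#' probability and conditional fixation time once, then evaluates the
#' effective rate of evolution `1/(t1 + t2)` over the mutation-rate grid
#' and reports it relative to the complete graph. At low mutation rates
#' the amplifying structures win (mutant supply limits the rate, so high
#' `rho` pays); at high rates the complete graph wins (fixation time
#' dominates); suitable balanced bipartite graphs take the intermediate
#' regime.
#'
#' @param structures Character vector of structure tokens (see
#'   [lumped_structure_stats()]).
#' @param n Population size.
#' @param r Mutant relative fitness.
#' @param mu_grid Mutation rates (e.g. [mu_log_grid()]).
#' @inheritParams lumped_structure_stats
#' @return Data frame: `structure`, `mu`, `rho`, `fix_time_steps`, `rate`,
#'   `relative_rate` (vs `"complete"`).
#' @export
run_rate_curves <- function(structures, n, r, mu_grid,
                            scheme = c("uniform", "temperature"),
                            part_convention = c("total", "large-part")) {
  scheme <- match.arg(scheme)
  part_convention <- match.arg(part_convention)
  if (length(mu_grid) < 1L) stop("mu_grid must be non-empty")
  stats <- lapply(structures, lumped_structure_stats, n = n, r = r,
                  scheme = scheme, part_convention = part_convention)
  ref <- lumped_structure_stats("complete", n, r, scheme, part_convention)
  rate_ref <- effective_rate(n, mu_grid, ref$rho, ref$cond_fix_time)
  do.call(rbind, lapply(seq_along(structures), function(i) {
    st <- stats[[i]]
    rate <- effective_rate(n, mu_grid, st$rho, st$cond_fix_time)
    data.frame(structure = structures[i], mu = mu_grid,
               rho = st$rho, fix_time_steps = st$cond_fix_time,
               rate = rate, relative_rate = rate / rate_ref)
  }))
}

#' Simulated probability-time tradeoff for graph families at fixed size
#'
#' Builds one or more instances of each requested family at total
#' population size `n`, estimates fixation probability and times by Monte
#' Carlo, and -- for families with an exact lumped solver (complete, star,
#' balanced/weighted bipartite) -- attaches the exact values as a
#' cross-check. Family tokens: `"complete"`, `"star"`, `"cycle"`,
#' `"tree"`, `"er:<p>"`, `"star+<k>"`, `"cycle+<k>"`,
#' `"balanced:<alpha>"`, `"weighted:<alpha>"`.
#'
#' @param n Total population size.
#' @param r Mutant relative fitness.
#' @param scheme Initialization scheme.
#' @param families Character vector of family tokens.
#' @param n_runs Monte Carlo runs per instance.
#' @param seed Master seed; instance seeds are derived deterministically.
#' @param n_reps Instances per random family.
#' @param fast_forward Passed to [estimate()] (recommended for weighted
#'   bipartite families, whose trajectories are dominated by self-loop
#'   holds).
#' @return Data frame with one row per instance: estimates with standard
#'   errors and exact values where available.
#' @export
run_family_tradeoff <- function(n, r, scheme = c("uniform", "temperature"),
                                families, n_runs = 1e4, seed = 1,
                                n_reps = 1, fast_forward = FALSE) {
  scheme <- match.arg(scheme)
  rows <- list()
  for (fi in seq_along(families)) {
    fam <- families[fi]
    for (rep in seq_len(n_reps)) {
      gseed <- seed + 7919L * fi + rep
      g <- family_instance(fam, n, gseed)
      est <- estimate(g, r, init = scheme, n_runs = n_runs,
                      seed = gseed, fast_forward = fast_forward)
      ex <- family_exact(fam, n, r, scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, rep = rep, n = g$n, r = r, scheme = scheme,
        n_runs = as.integer(n_runs), seed = gseed,
        rho_hat = est$rho_hat, rho_se = est$rho_se,
        fix_time_hat = est$fix_time_hat, fix_time_se = est$fix_time_se,
        absorb_time_hat = est$absorb_time_hat,
        absorb_time_se = est$absorb_time_se,
        rho_exact = if (is.null(ex)) NA_real_ else ex$rho,
        fix_time_exact = if (is.null(ex)) NA_real_ else ex$cond_fix_time)
    }
  }
  do.call(rbind, rows)
}

family_instance <- function(token, n, seed) {
  tok <- strsplit(token, ":", fixed = TRUE)[[1]]
  kind <- tok[1]
  if (grepl("^star\\+", kind))
    return(make_star_plus_edges(n, as.integer(sub("^star\\+", "", kind)),
                                seed))
  if (grepl("^cycle\\+", kind))
    return(make_cycle_plus_edges(n, as.integer(sub("^cycle\\+", "", kind)),
                                 seed))
  switch(kind,
    complete = make_complete(n),
    star = make_star(n),
    cycle = make_cycle(n),
    tree = make_random_tree(n, seed),
    er = make_erdos_renyi(n, as.numeric(tok[2]), seed),
    balanced = {
      p <- bipartite_parts_for_total(n, as.numeric(tok[2]))
      make_complete_bipartite(p$m, p$s, 0)
    },
    weighted = {
      alpha <- as.numeric(tok[2])
      p <- bipartite_parts_for_total(n, alpha)
      make_complete_bipartite(p$m, p$s,
                              p$m^(1 - alpha / 2) - p$m^(1 - alpha))
    },
    stop("unknown family token: ", token))
}

family_exact <- function(token, n, r, scheme) {
  kind <- strsplit(token, ":", fixed = TRUE)[[1]][1]
  if (kind %in% c("complete", "star", "balanced", "weighted"))
    lumped_structure_stats(token, n, r, scheme)
  else NULL
}

#' Per-vertex solution table for CSV export
#'
#' @param x A `fixation_solution`.
#' @param row.names,optional Ignored (S3 signature compatibility).
#' @param graph_id Identifier column value (e.g. the graph6 string).
#' @param ... Unused.
#' @return Data frame: `graph_id`, `vertex`, `rho`, `absorb_time_steps`,
#'   `cond_fix_time_steps`.
#' @export
as.data.frame.fixation_solution <- function(x, row.names = NULL,
                                            optional = FALSE,
                                            graph_id = NA_character_, ...) {
  data.frame(graph_id = graph_id, vertex = seq_len(x$n), rho = x$rho,
             absorb_time_steps = x$absorb_time,
             cond_fix_time_steps = x$cond_fix_time)
}
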