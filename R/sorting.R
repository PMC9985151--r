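#' Optimal sorting scenarios
#'
#' `sort_rank` builds a scenario of basic operations (all six kinds)
#' transforming `A` into `B` with total weight exactly the rank distance;
#' intermediates may be relaxed (lone extremities) because of substitutions.
#' `sort_rank_indel` restricts to the five content-safe operations (no
#' extremity substitutions); every intermediate is a whole-marker genome and
#' the total weight is exactly the rank-indel distance.
#'
#' The construction is a verified greedy: candidate operations are read off
#' the current genome and the target (joins and cuts, double swaps, whole
#' (semi-)chromosome deletions, insertions of maximal target-material runs,
#' and substitutions in rank mode) and a candidate is accepted only if it
#' decreases the respective distance by exactly its weight.  Because the
#' distance equals the optimal scenario weight, such a step always exists;
#' candidates are scanned in a deterministic order so output is reproducible.
#'
#' @param A,B `genome` objects over the same universe (`sort_rank_indel`
#'   additionally requires both to be whole-marker).
#' @return an object of class `scenario`: list with `source`, `target`,
#'   `steps` (list of `genome_op`) and `total_weight`.
#' @examples
#' u <- make_universe(c("a", "x", "y"))
#' A <- genome_from_chromosomes(u, list(c("a", "x")))
#' B <- genome_from_chromosomes(u, list(c("a", "y")))
#' sort_rank(A, B)$total_weight        # 4
#' sort_rank_indel(A, B)$total_weight  # 6
#' @export
sort_rank <- function(A, B) {
  sort_scenario(A, B, mode = "rank")
}

#' @rdname sort_rank
#' @export
sort_rank_indel <- function(A, B) {
  if (!is_whole_marker(A) || !is_whole_marker(B)) {
    abort_ri("rank-indel sorting requires whole-marker genomes",
             "ri_invalid_genome")
  }
  sort_scenario(A, B, mode = "rank_indel")
}

sort_scenario <- function(A, B, mode) {
  if (!same_universe(A$universe, B$universe)) {
    abort_ri("genomes must share a marker universe", "ri_universe_mismatch")
  }
  dist_fun <- if (mode == "rank") {
    rank_distance
  } else {
    rank_indel_distance
  }
  g <- A
  d <- dist_fun(g, B)
  steps <- list()
  while (d > 0L) {
    picked <- NULL
    for (op in candidate_ops(g, B, mode)) {
      if (!is_applicable(g, op)) next
      g2 <- apply_op(g, op)
      if (mode == "rank_indel" && !is_whole_marker(g2)) next
      d2 <- dist_fun(g2, B)
      if (d - d2 == op$weight) {
        picked <- op
        g <- g2
        d <- d2
        break
      }
    }
    if (is.null(picked)) {
      abort_ri("internal: no weight-realizing operation found (please report)",
               "ri_invalid_operation")
    }
    steps[[length(steps) + 1L]] <- picked
  }
  structure(list(source = A, target = B, steps = steps,
                 total_weight = sum(vapply(steps, `[[`, integer(1), "weight")),
                 mode = mode),
            class = "scenario")
}

# Candidate operations in deterministic priority order.  The list is
# exhaustive for cuts, joins, double swaps, deletions and substitutions;
# insertion candidates are the components of the target's adjacency + marker
# edge structure restricted to extremities absent from the current genome
# (inserting any other material can never pay for itself).
candidate_ops <- function(g, B, mode) {
  adj <- g$adj
  badj <- B$adj
  ops <- list()
  push <- function(op) ops[[length(ops) + 1L]] <<- op

  free <- which(adj == seq_along(adj))
  # 1. joins of target adjacencies between current free ends
  for (x in free) {
    y <- badj[x]
    if (y > x && y != x && adj[y] == y) push(op_join(x, y))
  }
  # 2. cuts of adjacencies not shared with the target
  apairs <- which(adj > seq_along(adj))
  for (x in apairs) {
    if (badj[x] != adj[x]) push(op_cut(x, adj[x]))
  }
  # 3. double swaps over pairs of current adjacencies, target-creating first
  if (length(apairs) >= 2L) {
    swaps <- list()
    later <- list()
    for (ii in seq_len(length(apairs) - 1L)) {
      for (jj in (ii + 1L):length(apairs)) {
        a <- apairs[ii]; b <- adj[apairs[ii]]
        c_ <- apairs[jj]; d_ <- adj[apairs[jj]]
        for (add in list(list(c(a, c_), c(b, d_)), list(c(a, d_), c(b, c_)))) {
          op <- op_double_swap(list(c(a, b), c(c_, d_)), add)
          creates <- any(vapply(add, function(p) badj[p[1]] == p[2],
                                logical(1)))
          if (creates) swaps[[length(swaps) + 1L]] <- op
          else later[[length(later) + 1L]] <- op
        }
      }
    }
    for (op in swaps) push(op)
    for (op in later) push(op)
  }
  # 4. deletions of whole (semi-)chromosomes, target-absent material first
  chroms <- genome_to_chromosomes(g)
  dels <- list()
  later <- list()
  for (ch in chroms) {
    op <- op_delete(ch)
    if (all(badj[ch$extremities] == 0L)) dels[[length(dels) + 1L]] <- op
    else later[[length(later) + 1L]] <- op
  }
  for (op in dels) push(op)
  for (op in later) push(op)
  # 5. insertions of target material absent from g
  for (ch in insertion_candidates(g, B)) push(op_insert(ch))
  # 6. extremity substitutions (rank mode only), content-fixing first
  if (mode == "rank") {
    present <- which(adj > 0L)
    absent <- which(adj == 0L)
    prio_old <- present[badj[present] == 0L]
    prio_new <- absent[badj[absent] != 0L]
    for (x in prio_old) for (y in prio_new) push(op_substitute(x, y))
    for (x in present) {
      for (y in absent) {
        if (!(x %in% prio_old && y %in% prio_new)) push(op_substitute(x, y))
      }
    }
  }
  # 7. joins of arbitrary free-end pairs (needed when no target adjacency
  # is directly formable), then cuts of shared adjacencies for completeness
  if (length(free) >= 2L) {
    for (ii in seq_len(length(free) - 1L)) {
      for (jj in (ii + 1L):length(free)) {
        x <- free[ii]; y <- free[jj]
        if (badj[x] != y) push(op_join(x, y))
      }
    }
  }
  for (x in apairs) {
    if (badj[x] == adj[x]) push(op_cut(x, adj[x]))
  }
  ops
}

# Insertable (semi-)chromosomes of target material absent from g: the
# components of the graph on absent extremities whose edges are (i) the
# target adjacencies, (ii) the marker edges, and (iii) one "closing" edge
# per AA-null path of BG(g, target), pairing its two endpoints.  Closing
# edges let an insertion turn an AA-null path into a cycle, which is where
# the optimal scenarios place the freedom of the inserted chromosome's
# internal adjacencies.
insertion_candidates <- function(g, B) {
  adj <- g$adj
  badj <- B$adj
  absent <- adj == 0L
  n2 <- length(adj)
  # closing edges from AA-null paths (their A-null nodes are the endpoints)
  link <- integer(n2)
  for (comp in classify_components(build_bg(g, B))) {
    if (comp$kind != "AA_null") next
    ends <- comp$nodes[adj[comp$nodes] == 0L]
    if (length(ends) == 2L && badj[ends[1]] != ends[2]) {
      link[ends[1]] <- ends[2]
      link[ends[2]] <- ends[1]
    }
  }
  visited <- logical(n2)
  out <- list()
  for (start in seq_len(n2)) {
    if (!absent[start] || visited[start] ||
        (badj[start] == 0L && link[start] == 0L)) next
    comp <- start
    visited[start] <- TRUE
    head <- 1L
    while (head <= length(comp)) {
      x <- comp[head]
      head <- head + 1L
      nb <- integer(0)
      p <- ext_partner(x)
      if (absent[p]) nb <- p
      if (badj[x] > 0L && badj[x] != x && absent[badj[x]]) {
        nb <- c(nb, badj[x])
      }
      if (link[x] > 0L) nb <- c(nb, link[x])
      for (y in nb) {
        if (!visited[y]) { visited[y] <- TRUE; comp <- c(comp, y) }
      }
    }
    comp <- sort(comp)
    adjs <- list()
    for (x in comp) {
      y <- badj[x]
      if (y > x && y != x && y %in% comp) adjs[[length(adjs) + 1L]] <- c(x, y)
      z <- link[x]
      if (z > x && z %in% comp) adjs[[length(adjs) + 1L]] <- c(x, z)
    }
    kind <- if (length(adjs) > 0L && is_cycle_comp(comp, adjs)) {
      "circular"
    } else {
      "linear"
    }
    out[[length(out) + 1L]] <- structure(
      list(kind = kind, markers = NULL, extremities = comp,
           adjacencies = adjs),
      class = "chromosome")
  }
  out
}

# comp forms a cycle when every extremity is covered by both a B-adjacency
# and a marker edge inside comp.
is_cycle_comp <- function(comp, adjs) {
  in_adj <- unlist(adjs)
  all(comp %in% in_adj) && all(ext_partner(comp) %in% comp)
}

#' Replay and validate a scenario
#'
#' Applies the steps in order, checking applicability at every stage, and
#' additionally verifies the matrix route: the sum of the operation matrices
#' added to the source's genomic matrix must equal the final genome's
#' matrix, with every intermediate matrix genomic.
#'
#' @param scenario a `scenario`.
#' @param check_matrices verify the matrix route too (quadratic; default
#'   TRUE, intended for testing and small genomes).
#' @return the final `genome`, invisibly; errors on any violation.
#' @export
replay_scenario <- function(scenario, check_matrices = TRUE) {
  g <- scenario$source
  M <- if (check_matrices) to_matrix(g)
  for (op in scenario$steps) {
    if (check_matrices) {
      M <- M + operation_matrix(op, g)
    }
    g <- apply_op(g, op)
    if (check_matrices && !isTRUE(is_genomic_matrix(M))) {
      abort_ri("scenario intermediate is not genomic", "ri_invalid_operation")
    }
    if (check_matrices && !identical(M, to_matrix(g))) {
      abort_ri("matrix route diverged from symbolic application",
               "ri_invalid_operation")
    }
  }
  invisible(g)
}

#' @export
print.scenario <- function(x, ...) {
  cat(format_scenario(x), sep = "\n")
  invisible(x)
}

#' Serialize a scenario
#'
#' One operation per line (kind, payload, weight, tab separated) after a
#' header carrying the mode and total weight.
#'
#' @param scenario a `scenario`.
#' @param labels optional `c(source, target)` labels for the header.
#' @return character vector of lines.
#' @export
format_scenario <- function(scenario, labels = c("A", "B")) {
  u <- scenario$source$universe
  c(sprintf("# scenario\t%s -> %s\tmode=%s\ttotal_weight=%d",
            labels[1], labels[2], scenario$mode, scenario$total_weight),
    vapply(scenario$steps, format_op, character(1), universe = u))
}
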