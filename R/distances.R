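#' Rank distance via the linear-time component scan
#'
#' Breadth-first traversal of the augmented breakpoint graph computing, for
#' each component, the score \eqn{s} = (number of A-null extremities) -
#' (number of B-null extremities).  Starting from \eqn{d = 2n}, every
#' zero-score component decreases \eqn{d} by 1 if it is a path and by 2 if it
#' is a cycle; the result equals the rank of \eqn{B - A}.  Runs in
#' \eqn{O(n)}.
#'
#' @param A,B adjacency vectors of equal length `2n` (`[i] = j` for an
#'   adjacency `{i, j}`, `i` for a free end, `0` for an absent extremity), or
#'   `genome` objects over the same universe.
#' @return the rank distance, a non-negative integer.
#' @export
rank_distance_bfs <- function(A, B) {
  if (inherits(A, "genome")) {
    if (!inherits(B, "genome") || !same_universe(A$universe, B$universe)) {
      abort_ri("genomes must share a marker universe", "ri_universe_mismatch")
    }
    A <- A$adj
    B <- B$adj
  }
  A <- as.integer(A)
  B <- as.integer(B)
  n2 <- length(A)
  if (length(B) != n2) {
    abort_ri("adjacency vectors must have equal length", "ri_dimension")
  }
  check_involution(A)
  check_involution(B)
  d <- n2
  visited <- logical(n2)
  for (start in seq_len(n2)) {
    if (visited[start]) next
    nodes <- start
    visited[start] <- TRUE
    head <- 1L
    edge_ends <- 0L
    s <- 0L
    while (head <= length(nodes)) {
      x <- nodes[head]
      head <- head + 1L
      if (A[x] == 0L) s <- s + 1L
      if (B[x] == 0L) s <- s - 1L
      ya <- A[x]
      if (ya > 0L && ya != x) {
        edge_ends <- edge_ends + 1L
        if (!visited[ya]) { visited[ya] <- TRUE; nodes <- c(nodes, ya) }
      }
      yb <- B[x]
      if (yb > 0L && yb != x) {
        edge_ends <- edge_ends + 1L
        if (!visited[yb]) { visited[yb] <- TRUE; nodes <- c(nodes, yb) }
      }
    }
    if (s == 0L) {
      is_cycle <- edge_ends %/% 2L == length(nodes)
      d <- d - if (is_cycle) 2L else 1L
    }
  }
  d
}

check_involution <- function(v) {
  n2 <- length(v)
  if (any(v < 0L | v > n2)) {
    abort_ri("adjacency vector entries out of range", "ri_invalid_genome")
  }
  on <- which(v > 0L)
  if (any(v[v[on]] != on)) {
    abort_ri("adjacency vector is not an involution on its support",
             "ri_invalid_genome")
  }
  invisible(v)
}

#' Distance formulas from component statistics
#'
#' `rank_distance_formula` evaluates \eqn{d_r = 2n - 2c - p_0 - p_{AB}};
#' `rank_indel_formula` evaluates \eqn{d_i = 2n - 2c - p_0 + p_{AB}}.  The
#' two coincide exactly when there are no AB-null paths, and always satisfy
#' \eqn{d_i = d_r + 2 p_{AB} \ge d_r}.
#'
#' @param stats a `component_stats` from [bg_stats()] or [pair_stats()].
#' @return a non-negative integer.
#' @export
rank_distance_formula <- function(stats) {
  2L * stats$n - 2L * stats$c - stats$p0 - stats$pAB
}

#' @rdname rank_distance_formula
#' @export
rank_indel_formula <- function(stats) {
  2L * stats$n - 2L * stats$c - stats$p0 + stats$pAB
}

#' Rank and rank-indel distances between genomes
#'
#' `rank_distance` is the rank of the matrix difference \eqn{B - A}, the
#' minimum total weight of a scenario of the six basic operations.
#' `rank_indel_distance` is the minimum total weight when content may change
#' only through insertions and deletions of whole chromosomes (no extremity
#' substitutions); it is only defined for whole-marker genomes.
#'
#' @param A,B `genome` objects over the same universe.
#' @return a non-negative integer.
#' @examples
#' u <- make_universe(c("a", "x", "y"))
#' A <- genome_from_chromosomes(u, list(c("a", "x")))
#' B <- genome_from_chromosomes(u, list(c("a", "y")))
#' rank_distance(A, B)        # 4
#' rank_indel_distance(A, B)  # 6
#' @export
rank_distance <- function(A, B) {
  rank_distance_bfs(A, B)
}

#' @rdname rank_distance
#' @export
rank_indel_distance <- function(A, B) {
  if (!is_whole_marker(A) || !is_whole_marker(B)) {
    abort_ri("the rank-indel distance is defined for whole-marker genomes",
             "ri_invalid_genome")
  }
  rank_indel_formula(pair_stats(A, B))
}

#' Pairwise distance matrix over a genome set
#'
#' @param genomes named list of `genome` objects over a shared universe.
#' @param metric `"rank"` or `"rank_indel"`.
#' @return a symmetric numeric matrix with zero diagonal and the genome
#'   names as dimnames.
#' @export
distance_matrix <- function(genomes, metric = c("rank", "rank_indel")) {
  metric <- match.arg(metric)
  labels <- names(genomes)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort_ri("genomes must carry unique non-empty labels",
             "ri_duplicate_label")
  }
  if (length(genomes) < 2L) {
    abort_ri("need at least two genomes", "ri_parameter")
  }
  f <- if (metric == "rank") rank_distance else rank_indel_distance
  k <- length(genomes)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- f(genomes[[i]], genomes[[j]])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}
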