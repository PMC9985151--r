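#' Augmented breakpoint graph
#'
#' The augmented breakpoint graph `BG(A, B)` of two genomes over the same
#' universe has one node per extremity of the whole universe (including
#' extremities absent from both genomes), black edges for the adjacencies of
#' `A` and gray edges for those of `B`.  Every node has at most one black and
#' one gray edge, so components are paths and cycles; a shared adjacency
#' yields a pair of parallel black/gray edges forming a 2-cycle.
#'
#' @param A,B `genome` objects over the same universe.
#' @return An object of class `breakpoint_graph` with fields `universe`,
#'   `A_adj`, `B_adj` (adjacency vectors).
#' @export
build_bg <- function(A, B) {
  if (!same_universe(A$universe, B$universe)) {
    abort_ri("genomes must share a marker universe", "ri_universe_mismatch")
  }
  structure(list(universe = A$universe, A_adj = A$adj, B_adj = B$adj),
            class = "breakpoint_graph")
}

# Status of node x on one side: "paired", "free" or "null".
node_status <- function(adj, x) {
  if (adj[x] == 0L) "null" else if (adj[x] == x) "free" else "paired"
}

#' Decompose and classify breakpoint graph components
#'
#' Paths are classified by their two endpoint statuses: both free ends give a
#' proper path; free plus A-null (B-null) gives an A-null (B-null) path; two
#' A-null (B-null) ends give an AA-null (BB-null) path; one of each gives an
#' AB-null path.  Degree-0 nodes follow the same rules applied to the node's
#' two sides, with the convention that a node null in both genomes is a
#' proper path (the convention compatible with both distance formulas).
#' Components are emitted in ascending order of their minimum node index.
#'
#' @param bg a `breakpoint_graph`.
#' @return list of components, each a list with `nodes`, `edges` (count),
#'   `kind` (one of `"cycle"`, `"proper"`, `"A_null"`, `"B_null"`,
#'   `"AA_null"`, `"BB_null"`, `"AB_null"`) and `score` (number of A-null
#'   minus number of B-null nodes in the component).
#' @export
classify_components <- function(bg) {
  Aa <- bg$A_adj
  Ba <- bg$B_adj
  n2 <- length(Aa)
  visited <- logical(n2)
  out <- list()
  for (start in seq_len(n2)) {
    if (visited[start]) next
    nodes <- start
    visited[start] <- TRUE
    head <- 1L
    edge_ends <- 0L
    while (head <= length(nodes)) {
      x <- nodes[head]
      head <- head + 1L
      for (y in c(Aa[x], Ba[x])) {
        if (y > 0L && y != x) {
          edge_ends <- edge_ends + 1L
          if (!visited[y]) { visited[y] <- TRUE; nodes <- c(nodes, y) }
        }
      }
    }
    edges <- edge_ends %/% 2L
    score <- sum(Aa[nodes] == 0L) - sum(Ba[nodes] == 0L)
    kind <- if (edges == length(nodes)) {
      "cycle"
    } else {
      classify_path(Aa, Ba, nodes)
    }
    out[[length(out) + 1L]] <- list(nodes = sort(nodes), edges = edges,
                                    kind = kind, score = score)
  }
  out
}

# Path kind from endpoint labels.  Endpoints are the nodes of degree <= 1;
# a degree-1 node is labeled by its edge-less side, an isolated node by both
# sides (both-null resolving to proper by convention).
classify_path <- function(Aa, Ba, nodes) {
  if (length(nodes) == 1L) {
    x <- nodes
    sa <- node_status(Aa, x)
    sb <- node_status(Ba, x)
    if (sa == "null" && sb == "null") return("proper")   # convention
    if (sa == "free" && sb == "free") return("proper")
    if (sa == "null") return("A_null")
    return("B_null")
  }
  labels <- character(0)
  for (x in nodes) {
    deg <- (Aa[x] > 0L && Aa[x] != x) + (Ba[x] > 0L && Ba[x] != x)
    if (deg != 1L) next
    if (Aa[x] == 0L) {
      labels <- c(labels, "A_null")
    } else if (Ba[x] == 0L) {
      labels <- c(labels, "B_null")
    } else {
      labels <- c(labels, "free")
    }
  }
  labels <- sort(labels)
  key <- paste(labels, collapse = "+")
  switch(key,
         "free+free" = "proper",
         "A_null+free" = "A_null",
         "B_null+free" = "B_null",
         "A_null+A_null" = "AA_null",
         "B_null+B_null" = "BB_null",
         "A_null+B_null" = "AB_null",
         abort_ri(sprintf("unclassifiable path endpoints: %s", key),
                  "ri_invalid_genome"))
}

#' Breakpoint graph component statistics
#'
#' Counts feeding both distance formulas: `c` cycles, `p` paths total, and
#' the per-kind path counts `p0` (proper), `pA`, `pB`, `pAA`, `pBB`, `pAB`.
#'
#' @param components output of [classify_components()].
#' @param universe the shared `marker_universe` (provides `n`).
#' @return a list of class `component_stats`.
#' @export
bg_stats <- function(components, universe) {
  kinds <- vapply(components, `[[`, character(1), "kind")
  s <- list(
    n = universe$n,
    c = sum(kinds == "cycle"),
    p = sum(kinds != "cycle"),
    p0 = sum(kinds == "proper"),
    pA = sum(kinds == "A_null"),
    pB = sum(kinds == "B_null"),
    pAA = sum(kinds == "AA_null"),
    pBB = sum(kinds == "BB_null"),
    pAB = sum(kinds == "AB_null")
  )
  structure(s, class = "component_stats")
}

#' @export
print.component_stats <- function(x, ...) {
  cat(sprintf("<component_stats> n=%d c=%d p0=%d pA=%d pB=%d pAA=%d pBB=%d pAB=%d\n",
              x$n, x$c, x$p0, x$pA, x$pB, x$pAA, x$pBB, x$pAB))
  invisible(x)
}

#' One-call component statistics for a genome pair
#'
#' @param A,B `genome` objects over the same universe.
#' @return a `component_stats`.
#' @export
pair_stats <- function(A, B) {
  bg <- build_bg(A, B)
  bg_stats(classify_components(bg), bg$universe)
}

#' DOT export of a breakpoint graph
#'
#' Black solid edges for genome A adjacencies, gray dashed for genome B;
#' intended for eyeballing small examples with graphviz.
#'
#' @param bg a `breakpoint_graph`.
#' @return a character scalar of DOT source.
#' @export
bg_to_dot <- function(bg) {
  u <- bg$universe
  lab <- function(i) ext_label(u, i)
  lines <- c("graph BG {", "  node [shape=circle];")
  for (i in seq_along(bg$A_adj)) {
    j <- bg$A_adj[i]
    if (j > i) lines <- c(lines, sprintf('  "%s" -- "%s" [color=black];',
                                         lab(i), lab(j)))
  }
  for (i in seq_along(bg$B_adj)) {
    j <- bg$B_adj[i]
    if (j > i) lines <- c(lines, sprintf('  "%s" -- "%s" [color=gray, style=dashed];',
                                         lab(i), lab(j)))
  }
  paste(c(lines, "}"), collapse = "\n")
}
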