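#' Genomes as adjacency involutions
#'
#' A genome over a marker universe is a set of present extremities
#' \eqn{V(A)} together with a set of adjacencies \eqn{E(A)} (unordered pairs
#' of distinct present extremities, each extremity in at most one adjacency).
#' The canonical runtime representation is the adjacency vector `adj` of
#' length \eqn{2n}: `adj[i] = j` if `{i, j}` is an adjacency, `adj[i] = i` if
#' extremity `i` is a present free end, and `adj[i] = 0` if it is absent.
#' This matches the column action of the genomic matrix on the basis vectors.
#'
#' Genomes are immutable values; all operations return new genomes.
#'
#' @param universe a `marker_universe`.
#' @param adj integer adjacency vector of length `2 * universe$n`.
#' @return An object of class `genome`.
#' @export
new_genome <- function(universe, adj) {
  n2 <- 2L * universe$n
  adj <- as.integer(adj)
  if (length(adj) != n2) {
    abort_ri("adjacency vector length must be 2n", "ri_dimension")
  }
  if (any(adj < 0L | adj > n2)) {
    abort_ri("adjacency vector entries out of range", "ri_invalid_genome")
  }
  on <- which(adj > 0L)
  if (any(adj[adj[on]] != on)) {
    abort_ri("adjacency vector is not an involution on its support",
             "ri_invalid_genome")
  }
  structure(list(universe = universe, adj = adj), class = "genome")
}

#' Build a genome from explicit extremities and adjacencies
#'
#' @param universe a `marker_universe`.
#' @param present character labels (`"a_t"` style) or integer indices of the
#'   present extremities.
#' @param adjacencies list of length-2 vectors (labels or indices).
#' @return a `genome`.
#' @export
genome_from_adjacencies <- function(universe, present, adjacencies = list()) {
  present <- resolve_ext(universe, present)
  n2 <- 2L * universe$n
  adj <- integer(n2)
  adj[present] <- present
  for (p in adjacencies) {
    p <- resolve_ext(universe, p)
    if (length(p) != 2L || p[1] == p[2]) {
      abort_ri("an adjacency is an unordered pair of two distinct extremities",
               "ri_invalid_genome")
    }
    if (!all(p %in% present)) {
      abort_ri("adjacency members must be present extremities",
               "ri_invalid_genome")
    }
    if (adj[p[1]] != p[1] || adj[p[2]] != p[2]) {
      abort_ri("an extremity can belong to at most one adjacency",
               "ri_invalid_genome")
    }
    adj[p[1]] <- p[2]
    adj[p[2]] <- p[1]
  }
  new_genome(universe, adj)
}

#' Resolve extremity labels to indices
#'
#' Accepts `"a_t"`/`"a_h"`-style labels or raw integer indices.
#'
#' @param universe a `marker_universe`.
#' @param x character labels or integer indices.
#' @return integer extremity indices.
#' @export
resolve_ext <- function(universe, x) {
  if (is.character(x)) {
    m <- sub("_[th]$", "", x)
    s <- sub("^.*_", "", x)
    ext_index(universe, m, s)
  } else {
    as.integer(x)
  }
}

#' @rdname new_genome
#' @param genome a `genome`.
#' @export
genome_extremities <- function(genome) which(genome$adj > 0L)

#' @rdname new_genome
#' @export
genome_adjacencies <- function(genome) {
  i <- which(genome$adj > 0L & genome$adj > seq_along(genome$adj))
  lapply(i, function(x) c(x, genome$adj[x]))
}

#' @rdname new_genome
#' @export
genome_free_ends <- function(genome) {
  which(genome$adj == seq_along(genome$adj))
}

#' Does every marker have both or neither extremity present?
#'
#' Whole-marker genomes are the biologically standard case; genomes with a
#' lone head or tail ("relaxed" genomes) arise only as intermediates of rank
#' sorting via extremity substitutions.
#'
#' @param genome a `genome`.
#' @return logical.
#' @export
is_whole_marker <- function(genome) {
  present <- genome$adj > 0L
  all(present[c(TRUE, FALSE)] == present[c(FALSE, TRUE)])
}

#' Validate a genome
#'
#' @param genome a `genome`.
#' @param mode `"whole_marker"` (default, rejects lone extremities) or
#'   `"relaxed"`.
#' @return the genome, invisibly; errors on violation.
#' @export
validate_genome <- function(genome, mode = c("whole_marker", "relaxed")) {
  mode <- match.arg(mode)
  if (!inherits(genome, "genome")) {
    abort_ri("not a genome", "ri_invalid_genome")
  }
  new_genome(genome$universe, genome$adj)  # re-runs structural checks
  if (mode == "whole_marker" && !is_whole_marker(genome)) {
    abort_ri("genome has a marker with only one extremity present",
             "ri_invalid_genome")
  }
  invisible(genome)
}

#' @export
print.genome <- function(x, ...) {
  ch <- genome_to_chromosomes(x)
  cat(sprintf("<genome> %d/%d extremities present, %d adjacencies, %d chromosome(s)\n",
              length(genome_extremities(x)), 2L * x$universe$n,
              length(genome_adjacencies(x)), length(ch)))
  for (c_ in ch) cat("  ", format_chromosome(c_), "\n", sep = "")
  invisible(x)
}

genome_equal <- function(a, b) {
  same_universe(a$universe, b$universe) && identical(a$adj, b$adj)
}

#' Chromosomes
#'
#' A chromosome is given as a vector of signed marker tokens (`"a"`,
#' `"-d"`): a forward marker reads tail-to-head left to right, a `-` prefix
#' reverses it.  Linear chromosomes have two free ends; circular ones have
#' none.  Semi-chromosomes (ending at a lone extremity) only arise from the
#' decomposition of relaxed genomes and are never built from tokens.
#'
#' @param markers character vector of signed marker tokens.
#' @param circular logical.
#' @return an object of class `chromosome` with fields `kind` and `markers`;
#'   decomposition results additionally carry `extremities` (the walk order)
#'   and `adjacencies`.
#' @export
chromosome <- function(markers, circular = FALSE) {
  if (length(markers) == 0L) {
    abort_ri("a chromosome needs at least one marker", "ri_invalid_genome")
  }
  structure(list(kind = if (circular) "circular" else "linear",
                 markers = as.character(markers)),
            class = "chromosome")
}

# Extremity walk of a token chromosome: forward marker -> (t, h).
chrom_ext_walk <- function(universe, chrom) {
  name <- sub("^-", "", chrom$markers)
  rev_ <- startsWith(chrom$markers, "-")
  t <- ext_index(universe, name, "t")
  h <- t + 1L
  as.integer(rbind(ifelse(rev_, h, t), ifelse(rev_, t, h)))
}

#' Assemble a genome from chromosomes
#'
#' Consecutive markers contribute an adjacency between the right extremity of
#' the first and the left extremity of the next; circular chromosomes add the
#' wrap-around adjacency; linear chromosome ends stay free.
#'
#' @param universe a `marker_universe`.
#' @param chromosomes list of `chromosome` objects (or bare token vectors,
#'   taken as linear).  Decomposition output (with an `extremities` field) is
#'   accepted too, making this the inverse of [genome_to_chromosomes()].
#' @return a `genome`.
#' @export
genome_from_chromosomes <- function(universe, chromosomes) {
  n2 <- 2L * universe$n
  adj <- integer(n2)
  seen <- integer(0)
  for (ch in chromosomes) {
    if (!inherits(ch, "chromosome")) ch <- chromosome(ch)
    if (!is.null(ch$extremities)) {
      walk <- ch$extremities
      pairs <- ch$adjacencies
    } else {
      walk <- chrom_ext_walk(universe, ch)
      k <- length(walk)
      pairs <- list()
      if (k > 2L) {
        right <- walk[seq(2L, k - 2L, by = 2L)]
        left <- walk[seq(3L, k - 1L, by = 2L)]
        pairs <- mapply(c, right, left, SIMPLIFY = FALSE)
      }
      if (identical(ch$kind, "circular")) {
        pairs[[length(pairs) + 1L]] <- c(walk[k], walk[1L])
      }
    }
    if (any(walk %in% seen) || anyDuplicated(walk)) {
      abort_ri("marker used twice across chromosomes", "ri_duplicate_marker")
    }
    seen <- c(seen, walk)
    adj[walk] <- walk
    for (p in pairs) { adj[p[1]] <- p[2]; adj[p[2]] <- p[1] }
  }
  new_genome(universe, adj)
}

# Walk one chromosome component starting from endpoint (or min node of a
# cycle) x0, alternating marker and adjacency edges.
walk_component <- function(adj, present, x0, circular) {
  lacks_adj <- adj[x0] == x0
  lacks_mk <- !present[ext_partner(x0)]
  if (!circular && lacks_adj && lacks_mk) {
    return(list(walk = x0, adjs = list()))
  }
  typ <- if (circular) "marker" else if (lacks_adj) "marker" else "adj"
  walk <- integer(0)
  adjs <- list()
  cur <- x0
  repeat {
    walk <- c(walk, cur)
    if (typ == "marker") {
      nxt <- ext_partner(cur)
    } else {
      nxt <- adj[cur]
      adjs[[length(adjs) + 1L]] <- c(cur, nxt)
    }
    if (circular && nxt == x0) break
    cur <- nxt
    typ <- if (typ == "marker") "adj" else "marker"
    if (!circular) {
      if (typ == "adj" && adj[cur] == cur) { walk <- c(walk, cur); break }
      if (typ == "marker" && !present[ext_partner(cur)]) {
        walk <- c(walk, cur)
        break
      }
    }
  }
  list(walk = walk, adjs = adjs)
}

#' Decompose a genome into chromosomes
#'
#' Walks the graph on present extremities whose edges are the adjacencies
#' plus the implicit marker edges (tail-head of the same present marker).
#' Components are circular chromosomes (cycles), linear chromosomes (paths
#' ending in free ends of whole markers) or semi-chromosomes (paths with at
#' least one lone-extremity end).  Deterministic: components are emitted in
#' ascending order of their minimum extremity index; paths are walked from
#' their lower-indexed endpoint, cycles from their lowest extremity.
#'
#' @param genome a `genome`.
#' @return list of `chromosome` objects carrying `kind`, signed marker
#'   tokens `markers` (lone extremities rendered as `"x_h"`-style labels),
#'   the `extremities` walk and the `adjacencies` used.
#' @export
genome_to_chromosomes <- function(genome) {
  adj <- genome$adj
  u <- genome$universe
  present <- adj > 0L
  visited <- logical(length(adj))
  out <- list()
  for (start in seq_along(adj)) {
    if (!present[start] || visited[start]) next
    comp <- component_of(adj, present, start)
    ends <- comp[vapply(comp, function(e) {
      adj[e] == e || !present[ext_partner(e)]
    }, logical(1))]
    circular <- length(ends) == 0L
    x0 <- if (circular) min(comp) else min(ends)
    w <- walk_component(adj, present, x0, circular)
    visited[w$walk] <- TRUE
    first <- w$walk[1L]
    last <- w$walk[length(w$walk)]
    semi <- !circular &&
      (!present[ext_partner(first)] || !present[ext_partner(last)])
    out[[length(out) + 1L]] <- structure(
      list(kind = if (circular) "circular" else if (semi) "semi" else "linear",
           markers = walk_tokens(u, w$walk),
           extremities = w$walk,
           adjacencies = w$adjs),
      class = "chromosome")
  }
  out
}

# Connected component of the adjacency + marker-edge graph containing start.
component_of <- function(adj, present, start) {
  comp <- start
  inq <- logical(length(adj))
  inq[start] <- TRUE
  head <- 1L
  while (head <= length(comp)) {
    x <- comp[head]
    head <- head + 1L
    p <- ext_partner(x)
    nb <- integer(0)
    if (present[p]) nb <- p
    if (adj[x] != x) nb <- c(nb, adj[x])
    for (y in nb) if (!inq[y]) { inq[y] <- TRUE; comp <- c(comp, y) }
  }
  comp
}

# Signed marker tokens read off an extremity walk; a lone extremity (its
# marker partner not following it in the walk) becomes an "x_h" label.
walk_tokens <- function(universe, walk) {
  tokens <- character(0)
  i <- 1L
  while (i <= length(walk)) {
    x <- walk[i]
    if (i < length(walk) && ext_partner(x) == walk[i + 1L]) {
      name <- universe$markers[ext_marker(x)]
      tokens <- c(tokens, if (x %% 2L == 1L) name else paste0("-", name))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ext_label(universe, x))
      i <- i + 1L
    }
  }
  tokens
}

format_chromosome <- function(chrom) {
  body <- paste(chrom$markers, collapse = " ")
  switch(chrom$kind,
         circular = paste0("(", body, ")"),
         semi = paste0("[", body, "]"),
         paste0(body, " $"))
}

#' @export
print.chromosome <- function(x, ...) {
  cat("<chromosome>", x$kind, paste(x$markers, collapse = " "), "\n")
  invisible(x)
}
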