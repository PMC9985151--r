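#' Simulation parameters
#'
#' Defaults follow the benchmark configuration: 20 chromosomes, 5000 genes,
#' insertion rate 0.2 and deletion rate 0.4 (event counts per branch are
#' Poisson with mean = branch length times the rate), duplication rate
#' pinned to 0 (duplicated markers are outside the model), and indel segment
#' lengths drawn from a Zipf distribution with exponent 3.5 (truncated at
#' `indel_max`).
#'
#' @param n_chromosomes number of linear chromosomes in the root genome.
#' @param n_genes number of markers in the root genome.
#' @param insertion_rate,deletion_rate non-negative rate factors.
#' @param duplication_rate must be 0.
#' @param indel_zipf Zipf exponent for indel segment length.
#' @param indel_max truncation of the Zipf length distribution.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_chromosomes = 20L, n_genes = 5000L,
                       insertion_rate = 0.2, deletion_rate = 0.4,
                       duplication_rate = 0, indel_zipf = 3.5,
                       indel_max = 50L) {
  if (duplication_rate != 0) {
    abort_ri("duplication_rate must be 0 (no repeated markers in this model)",
             "ri_parameter")
  }
  if (n_genes < 1L || n_chromosomes < 1L || n_chromosomes > n_genes) {
    abort_ri("need 1 <= n_chromosomes <= n_genes", "ri_parameter")
  }
  if (insertion_rate < 0 || deletion_rate < 0) {
    abort_ri("rates must be non-negative", "ri_parameter")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_genes = as.integer(n_genes),
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 duplication_rate = 0,
                 indel_zipf = indel_zipf,
                 indel_max = as.integer(indel_max)),
            class = "sim_params")
}

#' Random phylogeny for simulation
#'
#' Samples a binary topology uniformly (via `ape::rtree`) with exponential
#' branch lengths whose unit is the expected number of DCJ events on the
#' branch (indel event counts scale with the insertion/deletion rates).
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed optional RNG seed for reproducibility.
#' @param mean_branch mean branch length, in expected DCJ events.
#' @return an `ape` "phylo" tree with leaf labels `t1..tn`.
#' @export
random_tree <- function(n_taxa, seed = NULL, mean_branch = 10) {
  if (n_taxa < 3L) abort_ri("need at least 3 taxa", "ri_parameter")
  if (!is.null(seed)) set.seed(seed)
  ape::rtree(n_taxa,
             br = function(k) stats::rexp(k, rate = 1 / mean_branch))
}

#' Zipf-distributed segment lengths
#'
#' @param k how many draws.
#' @param exponent Zipf exponent (mass of length L proportional to
#'   `L^-exponent`).
#' @param max_len truncation.
#' @return integer vector.
#' @export
rzipf <- function(k, exponent = 3.5, max_len = 50L) {
  lens <- seq_len(max_len)
  sample(lens, k, replace = TRUE, prob = lens^(-exponent))
}

# -- mutable simulation state ------------------------------------------------
# adj: adjacency vector over extremities 2m-1/2m of marker ids 1..n_markers
# (0 = absent, i = free end, j = partner).  All simulator events act on
# whole markers, so states are always whole-marker genomes.

sim_root_state <- function(params) {
  n <- params$n_genes
  ord <- sample.int(n)
  sgn <- sample(c(1L, -1L), n, replace = TRUE)
  k <- params$n_chromosomes
  # split the marker order into k non-empty consecutive chromosomes
  cuts <- if (k > 1L) sort(sample(n - 1L, k - 1L)) else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  adj <- integer(2L * n)
  for (c_ in seq_len(k)) {
    ids <- ord[starts[c_]:ends[c_]]
    sg <- sgn[starts[c_]:ends[c_]]
    left <- ifelse(sg > 0L, 2L * ids - 1L, 2L * ids)
    right <- ifelse(sg > 0L, 2L * ids, 2L * ids - 1L)
    adj[c(left, right)] <- c(left, right)
    m <- length(ids)
    if (m > 1L) {
      adj[right[-m]] <- left[-1L]
      adj[left[-1L]] <- right[-m]
    }
  }
  list(adj = adj, n_markers = n)
}

sim_grow <- function(state, need) {
  if (need > length(state$adj)) {
    extra <- integer(max(need - length(state$adj), length(state$adj)))
    state$adj <- c(state$adj, extra)
  }
  state
}

# One random DCJ: pick two distinct cut points (adjacencies or free ends)
# uniformly and rejoin by a uniformly chosen non-identity reassembly.
sim_dcj <- function(state) {
  adj <- state$adj
  idx <- which(adj > 0L)
  pair_lo <- idx[adj[idx] > idx]
  free <- idx[adj[idx] == idx]
  cps <- c(pair_lo, free)
  if (length(cps) < 2L) return(state)
  pick <- sample(length(cps), 2L)
  p1 <- cps[pick[1]]
  p2 <- cps[pick[2]]
  is_adj1 <- adj[p1] != p1
  is_adj2 <- adj[p2] != p2
  if (is_adj1 && is_adj2) {
    a <- p1; b <- adj[p1]; c_ <- p2; d_ <- adj[p2]
    if (sample(2L, 1L) == 1L) {
      adj[a] <- c_; adj[c_] <- a; adj[b] <- d_; adj[d_] <- b
    } else {
      adj[a] <- d_; adj[d_] <- a; adj[b] <- c_; adj[c_] <- b
    }
  } else if (is_adj1 || is_adj2) {
    ab <- if (is_adj1) p1 else p2
    f <- if (is_adj1) p2 else p1
    a <- ab; b <- adj[ab]
    if (sample(2L, 1L) == 1L) {
      adj[a] <- f; adj[f] <- a; adj[b] <- b
    } else {
      adj[b] <- f; adj[f] <- b; adj[a] <- a
    }
  } else {
    adj[p1] <- p2
    adj[p2] <- p1
  }
  state$adj <- adj
  state
}

# Delete a contiguous run of up to len whole markers starting from a random
# present marker in a random direction; flanking extremities are rejoined.
sim_delete <- function(state, len) {
  adj <- state$adj
  heads <- seq(2L, length(adj), by = 2L)
  mk <- which(adj[heads] > 0L)
  if (length(mk) == 0L) return(state)
  m0 <- mk[sample(length(mk), 1L)]
  dir_tail_first <- sample(2L, 1L) == 1L
  first_ext <- if (dir_tail_first) 2L * m0 - 1L else 2L * m0
  last_ext <- ext_partner(first_ext)
  doomed <- m0
  while (length(doomed) < len) {
    nxt <- adj[last_ext]
    if (nxt == last_ext) break                     # chromosome end
    m <- ext_marker(nxt)
    if (m %in% doomed) break                       # wrapped a circle
    doomed <- c(doomed, m)
    last_ext <- ext_partner(nxt)
  }
  fl <- adj[first_ext]
  fr <- adj[last_ext]
  ext <- c(2L * doomed - 1L, 2L * doomed)
  fl_ok <- fl != first_ext && !(fl %in% ext)
  fr_ok <- fr != last_ext && !(fr %in% ext)
  adj[ext] <- 0L
  if (fl_ok && fr_ok) {
    adj[fl] <- fr
    adj[fr] <- fl
  } else if (fl_ok) {
    adj[fl] <- fl
  } else if (fr_ok) {
    adj[fr] <- fr
  }
  state$adj <- adj
  state
}

# Insert len fresh markers as a contiguous run at a uniformly chosen
# position (inside an adjacency, at a free end, or as a new chromosome when
# the genome is empty).
sim_insert <- function(state, len) {
  ids <- state$n_markers + seq_len(len)
  state$n_markers <- state$n_markers + len
  state <- sim_grow(state, 2L * state$n_markers)
  adj <- state$adj
  sg <- sample(c(1L, -1L), len, replace = TRUE)
  left <- ifelse(sg > 0L, 2L * ids - 1L, 2L * ids)
  right <- ifelse(sg > 0L, 2L * ids, 2L * ids - 1L)
  adj[c(left, right)] <- c(left, right)
  if (len > 1L) {
    adj[right[-len]] <- left[-1L]
    adj[left[-1L]] <- right[-len]
  }
  idx <- which(adj > 0L)
  idx <- idx[!(ext_marker(idx) %in% ids)]
  pair_lo <- idx[adj[idx] > idx]
  free <- idx[adj[idx] == idx]
  cps <- c(pair_lo, free)
  if (length(cps) > 0L) {
    p <- cps[sample(length(cps), 1L)]
    if (adj[p] != p) {
      x <- p; y <- adj[p]
      adj[x] <- left[1L]; adj[left[1L]] <- x
      adj[y] <- right[len]; adj[right[len]] <- y
    } else {
      adj[p] <- left[1L]; adj[left[1L]] <- p
    }
  }
  state$adj <- adj
  state
}

sim_branch <- function(state, length_, params) {
  n_dcj <- stats::rpois(1L, length_)
  n_ins <- stats::rpois(1L, length_ * params$insertion_rate)
  n_del <- stats::rpois(1L, length_ * params$deletion_rate)
  events <- sample(rep(c("dcj", "ins", "del"), c(n_dcj, n_ins, n_del)))
  for (e in events) {
    state <- switch(e,
      dcj = sim_dcj(state),
      ins = sim_insert(state, rzipf(1L, params$indel_zipf, params$indel_max)),
      del = sim_delete(state, rzipf(1L, params$indel_zipf, params$indel_max)))
  }
  state
}

# State -> list of token chromosomes with zero-padded marker names (the
# decomposition's extremity indices refer to the simulation universe, so only
# the signed tokens are kept; they resolve against any universe later).
sim_state_to_record <- function(state) {
  width <- max(6L, nchar(as.character(state$n_markers)))
  markers <- sprintf("m%0*d", width, seq_len(state$n_markers))
  u <- make_universe(markers)
  g <- new_genome(u, state$adj[seq_len(2L * state$n_markers)])
  lapply(genome_to_chromosomes(g), function(ch) {
    chromosome(ch$markers, circular = identical(ch$kind, "circular"))
  })
}

#' Evolve genomes along a tree
#'
#' Starts from a random whole-marker root genome (`n_genes` markers over
#' `n_chromosomes` linear chromosomes) and walks the tree from the root:
#' on a branch of length l it applies Poisson(l) random DCJ steps,
#' Poisson(l * insertion_rate) insertions of fresh markers and
#' Poisson(l * deletion_rate) deletions of contiguous runs, segment lengths
#' Zipf-distributed.  Inserted markers get globally fresh names, so no
#' marker is ever duplicated.
#'
#' @param tree a rooted binary "phylo" tree with branch lengths (units:
#'   expected DCJ events).
#' @param params a [sim_params()] object.
#' @param seed optional RNG seed.
#' @return list with `records` (named list, one chromosome list per leaf,
#'   ready for [genomes_from_records()]), `tree`, and `params`.
#' @export
evolve <- function(tree, params = sim_params(), seed = NULL) {
  if (!inherits(tree, "phylo")) {
    abort_ri("tree must be an ape phylo object", "ri_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", max(tree$edge))
  states[[root]] <- sim_root_state(params)
  # preorder over edges (ape trees from rtree are in preorder already, but
  # do not rely on it)
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  pending <- list(root)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  records <- list()
  walk <- function(node) {
    for (ei in children[[as.character(node)]]) {
      child <- tree$edge[ei, 2L]
      st <- sim_branch(states[[node]], tree$edge.length[ei], params)
      if (child <= n_tip) {
        records[[tree$tip.label[child]]] <<- sim_state_to_record(st)
      } else {
        states[[child]] <<- st
        walk(child)
      }
    }
  }
  walk(root)
  list(records = records[tree$tip.label], tree = tree, params = params)
}

#' One full simulation replicate
#'
#' Convenience wrapper: random tree, evolved leaf genomes, genomes over the
#' union universe, plus the simulation manifest.
#'
#' @param n_taxa leaves in the tree.
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param mean_branch mean branch length in expected DCJ events.
#' @return list with `tree`, `genomes` (named list over a shared universe),
#'   `records`, `params`, `seed`.
#' @export
simulate_replicate <- function(n_taxa = 20L, params = sim_params(),
                               seed = NULL, mean_branch = 10) {
  if (!is.null(seed)) set.seed(seed)
  tree <- random_tree(n_taxa, seed = NULL, mean_branch = mean_branch)
  ev <- evolve(tree, params, seed = NULL)
  genomes <- genomes_from_records(ev$records)
  list(tree = tree, genomes = genomes, records = ev$records,
       params = params, seed = seed)
}

#' Random whole-marker genome (testing / examples)
#'
#' Draws a random subset of the universe's markers and arranges them into
#' random linear and circular chromosomes.
#'
#' @param universe a `marker_universe`.
#' @param p_marker probability a marker is present.
#' @param p_circular probability a chromosome is circular.
#' @param mean_chrom_len mean markers per chromosome.
#' @return a `genome`.
#' @export
random_genome <- function(universe, p_marker = 0.8, p_circular = 0.25,
                          mean_chrom_len = 3) {
  keep <- universe$markers[stats::runif(universe$n) < p_marker]
  if (length(keep) == 0L) {
    return(new_genome(universe, integer(2L * universe$n)))
  }
  keep <- sample(keep)
  signs <- sample(c("", "-"), length(keep), replace = TRUE)
  tokens <- paste0(signs, keep)
  chroms <- list()
  i <- 1L
  while (i <= length(tokens)) {
    len <- min(1L + stats::rpois(1L, mean_chrom_len - 1), length(tokens) - i + 1L)
    chroms[[length(chroms) + 1L]] <-
      chromosome(tokens[i:(i + len - 1L)],
                 circular = stats::runif(1) < p_circular)
    i <- i + len
  }
  genome_from_chromosomes(universe, chroms)
}
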