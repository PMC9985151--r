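#' Basic rearrangement operations
#'
#' The six basic operations and their weights (weight = rank of the
#' operation's matrix):
#' * cut: remove one adjacency, weight 1;
#' * join: create one adjacency between two free ends, weight 1;
#' * double swap: exchange partners across two adjacencies, weight 2;
#' * deletion of a whole chromosome or semi-chromosome, weight = number of
#'   extremities removed (2k for a k-marker chromosome);
#' * insertion, the inverse, same weight;
#' * substitution of one present extremity by an absent one, weight 2.
#'
#' Payloads use extremity indices of the shared universe.  For indels the
#' payload is a `chromosome` carrying `extremities` and `adjacencies` (as
#' produced by [genome_to_chromosomes()]); token chromosomes are resolved
#' against the universe at application time.
#'
#' @param x,y extremity indices (cut/join: the adjacency; substitution:
#'   `old`/`new`).
#' @return an object of class `genome_op` with a `kind` and `weight`.
#' @name genome_op
NULL

#' @rdname genome_op
#' @export
op_cut <- function(x, y) {
  structure(list(kind = "cut", adjacency = sort(c(x, y)), weight = 1L),
            class = "genome_op")
}

#' @rdname genome_op
#' @export
op_join <- function(x, y) {
  structure(list(kind = "join", adjacency = sort(c(x, y)), weight = 1L),
            class = "genome_op")
}

#' @rdname genome_op
#' @param remove,add lists of two adjacencies each; `add` must re-match the
#'   same four extremities.
#' @export
op_double_swap <- function(remove, add) {
  old <- sort(unlist(remove))
  new <- sort(unlist(add))
  if (length(old) != 4L || anyDuplicated(old) || !identical(old, new)) {
    abort_ri("a double swap re-matches the four extremities of two adjacencies",
             "ri_invalid_operation")
  }
  if (setequal_pairs(remove, add)) {
    abort_ri("double swap must change the matching", "ri_invalid_operation")
  }
  structure(list(kind = "double_swap",
                 remove = lapply(remove, sort), add = lapply(add, sort),
                 weight = 2L),
            class = "genome_op")
}

setequal_pairs <- function(p1, p2) {
  k1 <- sort(vapply(p1, function(p) paste(sort(p), collapse = ","), ""))
  k2 <- sort(vapply(p2, function(p) paste(sort(p), collapse = ","), ""))
  identical(k1, k2)
}

#' @rdname genome_op
#' @param chrom a `chromosome` with `extremities`/`adjacencies` fields.
#' @export
op_delete <- function(chrom) {
  structure(list(kind = "chrom_deletion", chrom = chrom,
                 weight = length(chrom$extremities)),
            class = "genome_op")
}

#' @rdname genome_op
#' @export
op_insert <- function(chrom) {
  structure(list(kind = "chrom_insertion", chrom = chrom,
                 weight = length(chrom$extremities)),
            class = "genome_op")
}

#' @rdname genome_op
#' @param old,new extremity indices: `old` present in the genome, `new`
#'   absent from it.
#' @export
op_substitute <- function(old, new) {
  structure(list(kind = "extremity_substitution",
                 old = as.integer(old), new = as.integer(new), weight = 2L),
            class = "genome_op")
}

#' @export
print.genome_op <- function(x, ...) {
  cat("<op>", format_op(x), "\n")
  invisible(x)
}

format_op <- function(op, universe = NULL) {
  lab <- function(i) {
    if (is.null(universe)) paste0("e", i) else ext_label(universe, i)
  }
  payload <- switch(op$kind,
    cut = ,
    join = sprintf("{%s,%s}", lab(op$adjacency[1]), lab(op$adjacency[2])),
    double_swap = sprintf("%s -> %s",
      paste(vapply(op$remove, function(p) sprintf("{%s,%s}", lab(p[1]), lab(p[2])), ""), collapse = " "),
      paste(vapply(op$add, function(p) sprintf("{%s,%s}", lab(p[1]), lab(p[2])), ""), collapse = " ")),
    chrom_deletion = ,
    chrom_insertion = paste(lab(op$chrom$extremities), collapse = " "),
    extremity_substitution = sprintf("%s -> %s", lab(op$old), lab(op$new)))
  sprintf("%s\t%s\t%d", op$kind, payload, op$weight)
}

#' Matrix of an operation
#'
#' Returns the matrix \eqn{X} with `to_matrix(apply_op(A, op)) ==
#' to_matrix(A) + X`.  The genome provides the universe, and for an
#' extremity substitution also the current partner of the replaced
#' extremity.  The rank of \eqn{X} always equals the operation's weight.
#'
#' @param op a `genome_op`.
#' @param genome the `genome` the operation is about to be applied to.
#' @return an integer matrix of dimension `2n`.
#' @export
operation_matrix <- function(op, genome) {
  n2 <- 2L * genome$universe$n
  X <- matrix(0L, n2, n2)
  put <- function(i, j, v) X[i, j] <<- X[i, j] + v
  switch(op$kind,
    cut = {
      x <- op$adjacency[1]; y <- op$adjacency[2]
      put(x, x, 1L); put(y, y, 1L); put(x, y, -1L); put(y, x, -1L)
    },
    join = {
      x <- op$adjacency[1]; y <- op$adjacency[2]
      put(x, x, -1L); put(y, y, -1L); put(x, y, 1L); put(y, x, 1L)
    },
    double_swap = {
      for (p in op$remove) { put(p[1], p[2], -1L); put(p[2], p[1], -1L) }
      for (p in op$add) { put(p[1], p[2], 1L); put(p[2], p[1], 1L) }
    },
    chrom_deletion = {
      sgn <- -1L
      X <- X + sgn * chrom_matrix(op$chrom, n2)
    },
    chrom_insertion = {
      X <- X + chrom_matrix(op$chrom, n2)
    },
    extremity_substitution = {
      x <- op$old; y <- op$new
      z <- genome$adj[x]
      if (z == x) {
        put(x, x, -1L); put(y, y, 1L)
      } else {
        put(x, z, -1L); put(z, x, -1L); put(y, z, 1L); put(z, y, 1L)
      }
    },
    abort_ri("unknown operation kind", "ri_invalid_operation"))
  X
}

# D(S) without the sign: adjacencies as off-diagonal pairs, unpaired
# extremities (free or semi ends) as diagonal entries.
chrom_matrix <- function(chrom, n2) {
  X <- matrix(0L, n2, n2)
  ext <- chrom$extremities
  in_adj <- unlist(chrom$adjacencies)
  for (p in chrom$adjacencies) {
    X[p[1], p[2]] <- X[p[1], p[2]] + 1L
    X[p[2], p[1]] <- X[p[2], p[1]] + 1L
  }
  for (e in setdiff(ext, in_adj)) X[e, e] <- 1L
  X
}

#' Is an operation applicable to a genome?
#'
#' An operation matrix X is applicable to A when A + X is again a genomic
#' matrix.  This checks the equivalent symbolic preconditions: a cut needs
#' its adjacency present; a join needs two present unpaired extremities; a
#' double swap needs both removed adjacencies; a deletion needs its
#' (semi-)chromosome exactly present (adjacencies as listed, remaining
#' extremities unpaired); an insertion needs all its extremities absent; a
#' substitution needs `old` present and `new` absent.
#'
#' @param genome a `genome`.
#' @param op a `genome_op`.
#' @return logical.
#' @export
is_applicable <- function(genome, op) {
  adj <- genome$adj
  switch(op$kind,
    cut = adj[op$adjacency[1]] == op$adjacency[2],
    join = {
      x <- op$adjacency[1]; y <- op$adjacency[2]
      x != y && adj[x] == x && adj[y] == y
    },
    double_swap = all(vapply(op$remove, function(p) adj[p[1]] == p[2],
                             logical(1))),
    chrom_deletion = {
      ext <- op$chrom$extremities
      in_adj <- unlist(op$chrom$adjacencies)
      ok <- all(vapply(op$chrom$adjacencies,
                       function(p) adj[p[1]] == p[2], logical(1)))
      loose <- setdiff(ext, in_adj)
      ok && all(adj[loose] == loose)
    },
    chrom_insertion = all(adj[op$chrom$extremities] == 0L),
    extremity_substitution = adj[op$old] != 0L && adj[op$new] == 0L &&
      op$old != op$new,
    FALSE)
}

#' Apply an operation
#'
#' @param genome a `genome`.
#' @param op a `genome_op` applicable to it.
#' @return the resulting `genome` (relaxed genomes can arise only from
#'   extremity substitutions and from indels of semi-chromosomes).
#' @export
apply_op <- function(genome, op) {
  if (!is_applicable(genome, op)) {
    abort_ri(sprintf("operation not applicable: %s", format_op(op)),
             "ri_not_applicable")
  }
  adj <- genome$adj
  switch(op$kind,
    cut = {
      x <- op$adjacency[1]; y <- op$adjacency[2]
      adj[x] <- x; adj[y] <- y
    },
    join = {
      x <- op$adjacency[1]; y <- op$adjacency[2]
      adj[x] <- y; adj[y] <- x
    },
    double_swap = {
      for (p in op$add) { adj[p[1]] <- p[2]; adj[p[2]] <- p[1] }
    },
    chrom_deletion = {
      adj[op$chrom$extremities] <- 0L
    },
    chrom_insertion = {
      ext <- op$chrom$extremities
      adj[ext] <- ext
      for (p in op$chrom$adjacencies) { adj[p[1]] <- p[2]; adj[p[2]] <- p[1] }
    },
    extremity_substitution = {
      x <- op$old; y <- op$new
      z <- adj[x]
      adj[x] <- 0L
      if (z == x) {
        adj[y] <- y
      } else {
        adj[y] <- z; adj[z] <- y
      }
    })
  new_genome(genome$universe, adj)
}

#' Inverse of an operation
#'
#' `apply_op(apply_op(g, op), inverse_op(op, g))` returns `g`.
#'
#' @param op a `genome_op`.
#' @param genome the genome `op` was applied to (needed to invert a
#'   substitution of a paired extremity).
#' @return a `genome_op`.
#' @export
inverse_op <- function(op, genome) {
  switch(op$kind,
    cut = op_join(op$adjacency[1], op$adjacency[2]),
    join = op_cut(op$adjacency[1], op$adjacency[2]),
    double_swap = op_double_swap(op$add, op$remove),
    chrom_deletion = op_insert(op$chrom),
    chrom_insertion = op_delete(op$chrom),
    extremity_substitution = op_substitute(op$new, op$old))
}
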