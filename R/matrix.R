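#' Genomic matrices
#'
#' The genomic matrix of a genome is the symmetric binary \eqn{2n \times 2n}
#' matrix whose column for extremity \eqn{x} is: the basis vector of its
#' adjacency partner \eqn{y} when \eqn{\{x, y\} \in E(A)}; \eqn{x} itself
#' when \eqn{x} is a present free end; and zero when \eqn{x} is absent.
#' A binary square matrix is genomic exactly when it is symmetric and its
#' square is diagonal with only 0/1 entries on the diagonal; the 1 entries
#' mark the present extremities.
#'
#' @param genome a `genome`.
#' @return `to_matrix`: an integer matrix with extremity labels as dimnames.
#' @export
to_matrix <- function(genome) {
  adj <- genome$adj
  n2 <- length(adj)
  M <- matrix(0L, n2, n2)
  on <- which(adj > 0L)
  M[cbind(adj[on], on)] <- 1L
  labs <- ext_label(genome$universe, seq_len(n2))
  dimnames(M) <- list(labs, labs)
  M
}

#' @rdname to_matrix
#' @param M a square integer matrix of even dimension.
#' @return `is_genomic_matrix`: logical.
#' @export
is_genomic_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || nrow(M) %% 2L != 0L) {
    abort_ri("a genomic matrix is square with even dimension", "ri_dimension")
  }
  if (!all(M %in% c(0, 1))) return(FALSE)
  if (!identical(dim(M), dim(t(M))) || any(M != t(M))) return(FALSE)
  M2 <- M %*% M
  d <- diag(M2)
  diag(M2) <- 0
  all(M2 == 0) && all(d %in% c(0, 1))
}

# Inverse of to_matrix for genomic matrices: recover the adjacency vector.
matrix_to_adj <- function(M) {
  n2 <- nrow(M)
  adj <- integer(n2)
  for (j in seq_len(n2)) {
    i <- which(M[, j] != 0)
    if (length(i) == 1L) adj[j] <- i
  }
  adj
}

#' Exact rank of an integer matrix
#'
#' Fraction-free (Bareiss) Gaussian elimination over the integers; no
#' floating-point tolerance is involved, so ranks of \eqn{\{-1, 0, 1\}}
#' difference matrices are exact.  Intermediate values are monitored and the
#' function aborts rather than risk losing exactness past \eqn{2^{52}}
#' (unreachable for the sparse genome-difference matrices used here).
#'
#' @param M an integer matrix (entries must be whole numbers).
#' @return the rank, a non-negative integer.
#' @examples
#' exact_rank(diag(4))          # 4
#' exact_rank(matrix(0, 2, 2))  # 0
#' @export
exact_rank <- function(M) {
  M <- as.matrix(M)
  if (any(M != round(M))) {
    abort_ri("exact_rank expects integer entries", "ri_parameter")
  }
  A <- matrix(as.numeric(M), nrow(M), ncol(M))
  nr <- nrow(A)
  nc <- ncol(A)
  r <- 0L
  prev <- 1
  for (col in seq_len(nc)) {
    if (r == nr) break
    rows <- (r + 1L):nr
    piv <- rows[A[rows, col] != 0][1]
    if (is.na(piv)) next
    if (piv != r + 1L) {
      tmp <- A[piv, ]; A[piv, ] <- A[r + 1L, ]; A[r + 1L, ] <- tmp
    }
    p <- A[r + 1L, col]
    if (r + 1L < nr) {
      below <- (r + 2L):nr
      A[below, ] <- (p * A[below, , drop = FALSE] -
                       outer(A[below, col], A[r + 1L, ])) / prev
      if (max(abs(A[below, ])) > 2^52) {
        abort_ri("exact_rank overflow guard tripped", "ri_parameter")
      }
    }
    prev <- p
    r <- r + 1L
  }
  r
}
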