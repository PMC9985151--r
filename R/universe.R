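#' Create a marker universe
#'
#' A marker universe is the global, ordered set of markers \eqn{G} shared by
#' all genomes in a comparison.  Each marker \eqn{g} contributes two
#' extremities, a tail \eqn{g_t} and a head \eqn{g_h}; the universe fixes the
#' bijection between extremities and the indices \eqn{1, \dots, 2n} used by
#' the matrix representation: the i-th marker (in input order) has tail index
#' \eqn{2i-1} and head index \eqn{2i}.
#'
#' @param markers character vector of unique marker names.
#' @return An object of class `marker_universe` with elements `markers` and
#'   `n` (the number of markers; there are `2 * n` extremities).
#' @examples
#' u <- make_universe(c("a", "b", "c", "d"))
#' ext_index(u, "a", "t")  # 1
#' ext_index(u, "d", "h")  # 8
#' @export
make_universe <- function(markers) {
  markers <- as.character(markers)
  if (length(markers) == 0L) {
    abort_ri("a marker universe needs at least one marker", "ri_parameter")
  }
  if (anyDuplicated(markers)) {
    abort_ri(
      sprintf("duplicate marker name(s): %s",
              paste(unique(markers[duplicated(markers)]), collapse = ", ")),
      "ri_duplicate_marker"
    )
  }
  structure(list(markers = markers, n = length(markers)),
            class = "marker_universe")
}

#' Extremity indexing helpers
#'
#' `ext_index` maps a marker name and side to its extremity index;
#' `ext_label` does the reverse, producing labels like `"a_t"`/`"a_h"`;
#' `ext_marker` gives the marker index owning an extremity and `ext_partner`
#' the index of the other extremity of the same marker.
#'
#' @param universe a `marker_universe`.
#' @param marker marker name(s).
#' @param side `"t"` (tail) or `"h"` (head), recycled.
#' @param i extremity index (or indices) in `1:(2 * universe$n)`.
#' @return integer indices or character labels.
#' @export
ext_index <- function(universe, marker, side = c("t", "h")) {
  m <- match(marker, universe$markers)
  if (anyNA(m)) {
    abort_ri(sprintf("unknown marker(s): %s",
                     paste(marker[is.na(m)], collapse = ", ")),
             "ri_parameter")
  }
  side <- rep_len(side, length(m))
  ifelse(side == "t", 2L * m - 1L, 2L * m)
}

#' @rdname ext_index
#' @export
ext_label <- function(universe, i) {
  paste0(universe$markers[(i + 1L) %/% 2L], ifelse(i %% 2L == 1L, "_t", "_h"))
}

#' @rdname ext_index
#' @export
ext_marker <- function(i) (i + 1L) %/% 2L

#' @rdname ext_index
#' @export
ext_partner <- function(i) ifelse(i %% 2L == 1L, i + 1L, i - 1L)

#' @export
print.marker_universe <- function(x, ...) {
  cat(sprintf("<marker_universe> %d markers: %s\n", x$n,
              paste(utils::head(x$markers, 12L), collapse = " ")))
  invisible(x)
}

same_universe <- function(a, b) identical(a$markers, b$markers)
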