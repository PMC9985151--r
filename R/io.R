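#' Read gene orders
#'
#' Plain-text multi-genome dialect: a `>` header starts a genome; each
#' following line holds one chromosome as whitespace-separated signed marker
#' tokens closed by a terminator, `$` for linear or `)` for circular.
#' A `-` prefix reverses a marker.  Files with one genome per file and files
#' holding several genomes are both accepted.
#'
#' @param path file to read.
#' @param strict reject unknown trailing tokens after the terminator
#'   (default TRUE).
#' @return named list of records; each record is a list of `chromosome`
#'   objects (tokens only, no universe resolution yet).
#' @export
read_gene_orders <- function(path, strict = TRUE) {
  lines <- readLines(path, warn = FALSE)
  records <- list()
  current <- NULL
  name <- NULL
  flush <- function() {
    if (!is.null(name)) {
      if (length(current) == 0L) {
        abort_ri(sprintf("genome '%s' has no chromosomes", name), "ri_parse")
      }
      records[[name]] <<- current
    }
  }
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      flush()
      name <- trimws(sub("^>", "", line))
      if (name == "") {
        abort_ri(sprintf("line %d: empty genome name", k), "ri_parse")
      }
      if (!is.null(records[[name]])) {
        abort_ri(sprintf("line %d: duplicate genome name '%s'", k, name),
                 "ri_duplicate_label")
      }
      current <- list()
      next
    }
    if (is.null(name)) {
      abort_ri(sprintf("line %d: chromosome before any '>' header", k),
               "ri_parse")
    }
    tokens <- strsplit(line, "\\s+")[[1]]
    term <- match(TRUE, tokens %in% c("$", ")"))
    if (is.na(term)) {
      abort_ri(sprintf("line %d: missing chromosome terminator ('$' or ')')", k),
               "ri_parse")
    }
    if (strict && term != length(tokens)) {
      abort_ri(sprintf("line %d: tokens after terminator", k), "ri_parse")
    }
    markers <- tokens[seq_len(term - 1L)]
    if (length(markers) == 0L) {
      abort_ri(sprintf("line %d: empty chromosome", k), "ri_parse")
    }
    if (any(markers %in% c("$", ")")) || any(sub("^-", "", markers) == "")) {
      abort_ri(sprintf("line %d: bad marker token", k), "ri_parse")
    }
    current[[length(current) + 1L]] <-
      chromosome(markers, circular = tokens[term] == ")")
  }
  flush()
  if (length(records) == 0L) {
    abort_ri("no genomes found (missing '>' header?)", "ri_parse")
  }
  # duplicate markers within one genome are an error
  for (nm in names(records)) {
    all_markers <- sub("^-", "",
                       unlist(lapply(records[[nm]], `[[`, "markers")))
    if (anyDuplicated(all_markers)) {
      abort_ri(sprintf("genome '%s' repeats marker '%s'", nm,
                       all_markers[duplicated(all_markers)][1]),
               "ri_duplicate_marker")
    }
  }
  records
}

#' Write gene orders
#'
#' @param records named list of chromosome lists (as from
#'   [read_gene_orders()] or [genome_to_chromosomes()]); only whole-marker
#'   content can be serialized.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(records, path) {
  out <- character(0)
  for (nm in names(records)) {
    out <- c(out, paste0(">", nm))
    for (ch in records[[nm]]) {
      term <- if (identical(ch$kind, "circular")) ")" else "$"
      out <- c(out, paste(c(ch$markers, term), collapse = " "))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Build genomes over the union universe
#'
#' The marker universe of a comparison is the lexicographically sorted union
#' of the marker names occurring in the input genomes (a fixed, reproducible
#' indexing).
#'
#' @param records named list of chromosome lists.
#' @param universe optional `marker_universe` to use instead of the union.
#' @return named list of `genome` objects sharing one universe.
#' @export
genomes_from_records <- function(records, universe = NULL) {
  if (is.null(universe)) {
    markers <- sort(unique(sub("^-", "",
                               unlist(lapply(records, function(r)
                                 unlist(lapply(r, `[[`, "markers")))))))
    universe <- make_universe(markers)
  }
  lapply(records, function(r) genome_from_chromosomes(universe, r))
}

#' Worked-example genome pairs
#'
#' Small fixtures used throughout the documentation and tests:
#' * `worked`: universe \{a, b, c, d\}; A = linear `a b -d` (marker c absent),
#'   B = linear `b c d` (marker a absent); rank distance 8.
#' * `indel_pair`: universe \{a, x, y\}; A = linear `a x`, B = linear `a y`;
#'   rank distance 4, rank-indel distance 6.
#' * `subst_pair`: universe \{b, c, w, x, y, z\}; A = linear `x b c y`,
#'   B = circular `(b c z)` plus linear `w`; rank distance 8, realizable by
#'   four extremity substitutions.  The B drawing is reconstructed from the
#'   documented substitution list (synthetic reconstruction, not a verbatim
#'   figure trace).
#'
#' @return named list; each element has `A`, `B` (genomes) and `note`.
#' @export
fixtures <- function() {
  u1 <- make_universe(c("a", "b", "c", "d"))
  worked <- list(
    A = genome_from_chromosomes(u1, list(c("a", "b", "-d"))),
    B = genome_from_chromosomes(u1, list(c("b", "c", "d"))),
    note = "worked example with d_r = 8; marker content differs on a and c"
  )
  u2 <- make_universe(c("a", "x", "y"))
  indel_pair <- list(
    A = genome_from_chromosomes(u2, list(c("a", "x"))),
    B = genome_from_chromosomes(u2, list(c("a", "y"))),
    note = "d_r = 4 but cut+delete+insert+join costs 6 (= d_i)"
  )
  u3 <- make_universe(c("b", "c", "w", "x", "y", "z"))
  subst_pair <- list(
    A = genome_from_chromosomes(u3, list(c("x", "b", "c", "y"))),
    B = genome_from_chromosomes(u3, list(chromosome(c("b", "c", "z"),
                                                    circular = TRUE),
                                         chromosome("w"))),
    note = paste("d_r = 8 via substitutions x_t->w_t, x_h->z_h, y_h->w_h,",
                 "y_t->z_t; B reconstructed from that substitution list")
  )
  list(worked = worked, indel_pair = indel_pair, subst_pair = subst_pair)
}

#' PHYLIP square distance matrices
#'
#' @param D symmetric numeric matrix with labels as dimnames.
#' @param path output file.
#' @param strict pad/truncate labels to 10 characters (classic PHYLIP);
#'   default FALSE writes relaxed labels separated by whitespace.
#' @return `path` invisibly (`write_phylip`); a labeled matrix
#'   (`read_phylip`).
#' @export
write_phylip <- function(D, path, strict = FALSE) {
  labs <- rownames(D)
  if (strict) labs <- formatC(substr(labs, 1, 10), width = -10)
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste(c(labs[i], format(D[i, ], trim = TRUE)), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1L) {
    abort_ri("malformed PHYLIP matrix", "ri_parse")
  }
  labs <- character(n)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    labs[i] <- parts[1]
    vals <- as.numeric(parts[-1])
    if (length(vals) != n || anyNA(vals)) {
      abort_ri(sprintf("malformed PHYLIP row %d", i), "ri_parse")
    }
    D[i, ] <- vals
  }
  dimnames(D) <- list(labs, labs)
  D
}
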