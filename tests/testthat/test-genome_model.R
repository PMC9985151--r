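test_that("marker universes fix the extremity indexing", {
  u <- make_universe(c("a", "b", "c", "d"))
  expect_equal(u$n, 4L)
  # a_t = e1, a_h = e2, ..., d_h = e8
  expect_equal(ext_index(u, c("a", "a", "d", "d"), c("t", "h", "t", "h")),
               c(1L, 2L, 7L, 8L))
  expect_equal(ext_label(u, c(1L, 8L)), c("a_t", "d_h"))
  expect_equal(ext_partner(c(1L, 2L, 7L)), c(2L, 1L, 8L))

  u1 <- make_universe("x")
  expect_equal(ext_index(u1, c("x", "x"), c("t", "h")), c(1L, 2L))

  expect_error(make_universe(c("a", "a")), class = "ri_duplicate_marker")
  expect_error(ext_index(u, "zz", "t"), class = "ri_parameter")
})

test_that("genomes assemble from chromosomes with the adjacency rule", {
  u <- make_universe(c("a", "x", "y"))
  A <- genome_from_chromosomes(u, list(c("a", "x")))
  expect_setequal(genome_extremities(A), resolve_ext(u, c("a_t", "a_h", "x_t", "x_h")))
  expect_equal(genome_adjacencies(A),
               list(sort(resolve_ext(u, c("a_h", "x_t")))))

  u2 <- make_universe(c("b", "c", "z"))
  circ <- genome_from_chromosomes(u2, list(chromosome(c("b", "c", "z"),
                                                      circular = TRUE)))
  expect_length(genome_free_ends(circ), 0L)
  expect_setequal(
    vapply(genome_adjacencies(circ), function(p) paste(p, collapse = ","), ""),
    vapply(list(resolve_ext(u2, c("b_h", "c_t")), resolve_ext(u2, c("c_h", "z_t")),
                sort(resolve_ext(u2, c("z_h", "b_t")))),
           function(p) paste(sort(p), collapse = ","), ""))

  empty <- genome_from_chromosomes(u, list())
  expect_length(genome_extremities(empty), 0L)

  expect_error(genome_from_chromosomes(u, list(c("a", "a"))),
               class = "ri_duplicate_marker")
  expect_error(genome_from_chromosomes(u, list("a", c("x", "-a"))),
               class = "ri_duplicate_marker")
})

test_that("chromosome decomposition inverts assembly and handles semis", {
  # the worked-example genome: E = {{a_h,b_t},{b_h,d_h}}, marker c absent
  u <- make_universe(c("a", "b", "c", "d"))
  A <- genome_from_adjacencies(
    u, c("a_t", "a_h", "b_t", "b_h", "d_t", "d_h"),
    list(c("a_h", "b_t"), c("b_h", "d_h")))
  ch <- genome_to_chromosomes(A)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$kind, "linear")
  expect_equal(ch[[1]]$markers, c("a", "b", "-d"))

  # lone extremity -> one semi chromosome
  g <- genome_from_adjacencies(u, "a_h", list())
  ch <- genome_to_chromosomes(g)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$kind, "semi")
  expect_equal(ch[[1]]$markers, "a_h")

  # round trip on random genomes; decomposition partitions V(A)
  set.seed(101)
  for (i in 1:50) {
    p <- random_pair(sample(3:9, 1))
    g <- p$A
    chs <- genome_to_chromosomes(g)
    expect_setequal(unlist(lapply(chs, `[[`, "extremities")),
                    genome_extremities(g))
    g2 <- genome_from_chromosomes(p$u, chs)
    expect_genome_equal(g, g2)
  }
})

test_that("genomic matrices match the printed worked example", {
  u <- make_universe(c("a", "b", "c", "d"))
  A <- genome_from_chromosomes(u, list(c("a", "b", "-d")))
  MA <- to_matrix(A)
  rows <- c("10000000", "00100000", "01000000", "00000001",
            "00000000", "00000000", "00000010", "00010000")
  expected <- do.call(rbind, lapply(strsplit(rows, ""),
                                    function(r) as.integer(r)))
  expect_equal(unname(MA), expected)

  B <- genome_from_chromosomes(u, list(c("b", "c", "d")))
  MB <- to_matrix(B)
  # b_t and d_h are free ends (diagonal), marker a absent (zero rows)
  expect_equal(unname(diag(MB)), c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L))
  expect_true(all(MB[1:2, ] == 0L) && all(MB[, 1:2] == 0L))

  empty <- genome_from_chromosomes(u, list())
  expect_true(all(to_matrix(empty) == 0L))
})

test_that("is_genomic_matrix characterizes genome matrices", {
  u <- make_universe(c("a", "b", "c", "d"))
  A <- genome_from_chromosomes(u, list(c("a", "b", "-d")))
  expect_true(is_genomic_matrix(to_matrix(A)))
  expect_false(is_genomic_matrix(matrix(1, 2, 2)))
  expect_error(is_genomic_matrix(matrix(0, 3, 3)), class = "ri_dimension")

  set.seed(202)
  for (i in 1:100) {
    p <- random_pair(sample(2:8, 1))
    M <- to_matrix(p$A)
    expect_true(is_genomic_matrix(M))
    # diagonal of M^2 flags exactly the present extremities
    expect_equal(unname(which(diag(M %*% M) == 1L)), genome_extremities(p$A))
  }
  # relaxed genomes are genomic matrices too
  u8 <- make_universe(letters[1:6])
  for (i in 1:30) {
    g <- random_relaxed(u8)
    expect_true(is_genomic_matrix(to_matrix(g)))
  }
})

test_that("genome validation distinguishes whole-marker from relaxed", {
  u <- make_universe(c("a", "b"))
  g <- genome_from_adjacencies(u, c("a_t", "a_h"), list())
  expect_true(is_whole_marker(g))
  relaxed <- genome_from_adjacencies(u, "a_h", list())
  expect_false(is_whole_marker(relaxed))
  expect_error(validate_genome(relaxed), class = "ri_invalid_genome")
  expect_silent(validate_genome(relaxed, mode = "relaxed"))
  expect_error(new_genome(u, c(2L, 3L, 0L, 0L)), class = "ri_invalid_genome")
  expect_error(new_genome(u, c(1L, 1L, 1L)), class = "ri_dimension")
})
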