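test_that("operation matrices have rank equal to the declared weight", {
  u <- make_universe(c("a", "x", "y"))
  A <- fx$indel_pair$A  # linear a x

  # deleting the 1-marker chromosome (x): -x_t x_t' - x_h x_h', rank 2
  Acut <- apply_op(A, op_cut(resolve_ext(u, "a_h"), resolve_ext(u, "x_t")))
  chx <- genome_to_chromosomes(Acut)[[2]]
  expect_equal(chx$markers, "x")
  del <- op_delete(chx)
  Xdel <- operation_matrix(del, Acut)
  expect_equal(del$weight, 2L)
  expect_equal(exact_rank(Xdel), 2L)
  expect_equal(unname(diag(Xdel))[resolve_ext(u, c("x_t", "x_h"))],
               c(-1L, -1L))

  # cut has rank 1; insertion is the negated deletion
  cut <- op_cut(resolve_ext(u, "a_h"), resolve_ext(u, "x_t"))
  expect_equal(exact_rank(operation_matrix(cut, A)), 1L)
  expect_equal(operation_matrix(op_insert(chx), Acut),
               -operation_matrix(del, Acut))
})

test_that("applicability agrees between symbolic and matrix routes", {
  u <- fx$indel_pair$A$universe
  expect_true(is_applicable(fx$indel_pair$A,
                            op_cut(resolve_ext(u, "a_h"),
                                   resolve_ext(u, "x_t"))))
  # joining extremities that are already paired is not allowed
  expect_false(is_applicable(fx$indel_pair$A,
                             op_join(resolve_ext(u, "a_h"),
                                     resolve_ext(u, "x_t"))))

  set.seed(505)
  checked <- 0L
  while (checked < 500L) {
    p <- random_pair(sample(2:7, 1))
    for (op in rankindel:::candidate_ops(p$A, p$B, "rank")) {
      sym <- is_applicable(p$A, op)
      if (sym) {
        M <- to_matrix(p$A) + operation_matrix(op, p$A)
        expect_true(is_genomic_matrix(M))
        expect_equal(M, to_matrix(apply_op(p$A, op)))
        # declared weight always equals the matrix rank
        expect_equal(exact_rank(operation_matrix(op, p$A)), op$weight)
      }
      checked <- checked + 1L
      if (checked >= 500L) break
    }
  }
})

test_that("the documented unequal-content scenarios replay exactly", {
  # cut {a_h, x_t}; delete (x); insert (y); join {a_h, y_t}: total weight 6
  u <- fx$indel_pair$A$universe
  g <- fx$indel_pair$A
  steps <- list(op_cut(resolve_ext(u, "a_h"), resolve_ext(u, "x_t")))
  g <- apply_op(g, steps[[1]])
  del <- op_delete(genome_to_chromosomes(g)[[2]])
  g <- apply_op(g, del)
  ins <- op_insert(structure(list(kind = "linear", markers = "y",
                                  extremities = resolve_ext(u, c("y_t", "y_h")),
                                  adjacencies = list()),
                             class = "chromosome"))
  g <- apply_op(g, ins)
  jn <- op_join(resolve_ext(u, "a_h"), resolve_ext(u, "y_t"))
  g <- apply_op(g, jn)
  expect_genome_equal(g, fx$indel_pair$B)
  expect_equal(sum(steps[[1]]$weight, del$weight, ins$weight, jn$weight), 6L)

  # four extremity substitutions sort the second example at weight 8
  u7 <- fx$subst_pair$A$universe
  g <- fx$subst_pair$A
  total <- 0L
  for (s in list(c("x_t", "w_t"), c("x_h", "z_h"),
                 c("y_h", "w_h"), c("y_t", "z_t"))) {
    op <- op_substitute(resolve_ext(u7, s[1]), resolve_ext(u7, s[2]))
    expect_true(is_applicable(g, op))
    g <- apply_op(g, op)
    total <- total + op$weight
  }
  expect_genome_equal(g, fx$subst_pair$B)
  expect_equal(total, 8L)
})

test_that("operations invert cleanly", {
  set.seed(506)
  for (i in 1:40) {
    p <- random_pair(sample(3:7, 1))
    ops <- Filter(function(op) is_applicable(p$A, op),
                  rankindel:::candidate_ops(p$A, p$B, "rank"))
    if (length(ops) == 0L) next
    op <- ops[[sample(length(ops), 1L)]]
    g2 <- apply_op(p$A, op)
    back <- apply_op(g2, inverse_op(op, p$A))
    expect_genome_equal(back, p$A)
  }
})

test_that("segmental indels decompose into the stated composites", {
  # deleting k markers at a chromosome end = cut + chromosome deletion,
  # weight 2k + 1; an internal run = double swap extracting a circular
  # chromosome + its deletion, weight 2k + 2.
  u <- make_universe(letters[1:5])
  A <- genome_from_chromosomes(u, list(c("a", "b", "c", "d", "e")))
  i <- function(lbl) resolve_ext(u, lbl)

  # end deletion of (d e): cut {c_h, d_t}, delete linear (d e)
  g <- apply_op(A, op_cut(i("c_h"), i("d_t")))
  tail_ch <- Filter(function(ch) identical(ch$markers, c("d", "e")),
                    genome_to_chromosomes(g))[[1]]
  g <- apply_op(g, op_delete(tail_ch))
  expect_genome_equal(g, genome_from_chromosomes(u, list(c("a", "b", "c"))))
  expect_equal(1L + length(tail_ch$extremities), 2L * 2L + 1L)

  # internal deletion of (b c): double swap {a_h,b_t} x {c_h,d_t} ->
  # {a_h,d_t} + {b_t,c_h}, then delete the circular (b c)
  sw <- op_double_swap(list(c(i("a_h"), i("b_t")), c(i("c_h"), i("d_t"))),
                       list(c(i("a_h"), i("d_t")), c(i("b_t"), i("c_h"))))
  g <- apply_op(A, sw)
  circ <- Filter(function(ch) ch$kind == "circular",
                 genome_to_chromosomes(g))[[1]]
  g <- apply_op(g, op_delete(circ))
  expect_genome_equal(g, genome_from_chromosomes(u, list(c("a", "d", "e"))))
  expect_equal(sw$weight + length(circ$extremities), 2L * 2L + 2L)
})

test_that("whole-marker block substitution costs 2p + 2q", {
  # replacing block (x) by (w) in place, then (y) by (z): each a rank-4
  # matrix move (p = q = 1), so the pair of substitutions costs 8 -- and
  # provably does not reach the target genome (the rank distance is 8 but
  # the markers b, c stay unmoved).
  u <- fx$subst_pair$A$universe
  A <- fx$subst_pair$A
  step1 <- genome_from_chromosomes(u, list(c("w", "b", "c", "y")))
  step2 <- genome_from_chromosomes(u, list(c("w", "b", "c", "z")))
  r1 <- exact_rank(to_matrix(step1) - to_matrix(A))
  r2 <- exact_rank(to_matrix(step2) - to_matrix(step1))
  expect_equal(r1, 4L)
  expect_equal(r2, 4L)
  expect_equal(r1 + r2, 8L)
  expect_false(genome_equal(step2, fx$subst_pair$B))
  expect_equal(rank_distance(A, fx$subst_pair$B), 8L)
})

test_that("sorting meets its weight contract on the fixtures", {
  for (nm in names(fx)) {
    A <- fx[[nm]]$A
    B <- fx[[nm]]$B
    s <- sort_rank(A, B)
    expect_genome_equal(replay_scenario(s), B)
    expect_equal(s$total_weight, rank_distance(A, B))
    s2 <- sort_rank_indel(A, B)
    expect_genome_equal(replay_scenario(s2), B)
    expect_equal(s2$total_weight, rank_indel_distance(A, B))
    # indel-mode intermediates stay whole-marker
    g <- A
    for (op in s2$steps) {
      g <- apply_op(g, op)
      expect_true(is_whole_marker(g))
    }
  }
  # identity sorts with the empty scenario
  s <- sort_rank(fx$worked$A, fx$worked$A)
  expect_length(s$steps, 0L)
  expect_equal(s$total_weight, 0L)

  u <- make_universe(c("a", "b"))
  relaxed <- genome_from_adjacencies(u, "a_h", list())
  expect_error(sort_rank_indel(relaxed, fx$worked$A), class = "ri_invalid_genome")
})

test_that("scenario serialization carries the header and steps", {
  s <- sort_rank_indel(fx$indel_pair$A, fx$indel_pair$B)
  lines <- format_scenario(s, labels = c("A", "B"))
  expect_match(lines[1], "total_weight=6")
  expect_length(lines, length(s$steps) + 1L)
})
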