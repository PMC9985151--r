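# brute-force bipartition RF for the oracle route
rf_brute <- function(t1, t2) {
  splits <- function(tr) {
    tr <- ape::unroot(tr)
    tips <- sort(tr$tip.label)
    n <- length(tips)
    keys <- character(0)
    # enumerate all subsets appearing as an edge's leaf side
    for (e in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[e, 2]
      if (ch <= n) next
      side <- ape::extract.clade(tr, ch)$tip.label
      if (length(side) <= 1 || length(side) >= n - 1) next
      if (tips[1] %in% side) side <- setdiff(tips, side)
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
    unique(keys)
  }
  s1 <- splits(t1)
  s2 <- splits(t2)
  if (length(s1) + length(s2) == 0) return(0)
  (length(setdiff(s1, s2)) + length(setdiff(s2, s1))) / (length(s1) + length(s2))
}

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(606)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(rf_normalized(tr, est), 0)
    # branch lengths are recovered too: cophenetic distances match
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("neighbor joining handles 3 taxa and degenerate input", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # closed-form lengths: l_a = (3 + 4 - 5)/2 = 1, l_b = 2, l_c = 3
  expect_equal(sort(tr$edge.length), c(1, 2, 3))

  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_silent(tz <- neighbor_joining(Z))
  expect_true(all(tz$edge.length == 0))

  bad <- D; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), class = "ri_invalid_matrix")
  expect_error(neighbor_joining(D[1:2, 1:2]), class = "ri_parameter")
})

test_that("neighbor joining matches the reference implementation's topology", {
  set.seed(607)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    labs <- paste0("t", seq_len(n))
    D <- matrix(0, n, n, dimnames = list(labs, labs))
    v <- stats::runif(n * (n - 1) / 2, 1, 10)
    D[lower.tri(D)] <- v
    D <- D + t(D)
    expect_equal(rf_normalized(neighbor_joining(D), ape::nj(D)), 0)
  }
})

test_that("normalized RF agrees with brute force and the phangorn oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  expect_equal(rf_normalized(t1, t1), 0)

  set.seed(608)
  for (i in 1:25) {
    ta <- ape::rtree(6)
    tb <- ape::rtree(6)
    expect_equal(rf_normalized(ta, tb), rf_brute(ta, tb))
    expect_equal(rf_normalized(ta, tb),
                 as.numeric(phangorn::RF.dist(ta, tb, normalize = TRUE)))
    expect_equal(rf_normalized(ta, tb), rf_normalized(tb, ta))
  }

  t2 <- ape::rtree(6)
  t3 <- t2
  t3$tip.label[1] <- "weird"
  expect_error(rf_normalized(t2, t3), class = "ri_leaf_set")
})

test_that("quartet distance matches explicit enumeration", {
  qd_brute <- function(t1, t2) {
    tips <- sort(t1$tip.label)
    quartets <- utils::combn(tips, 4, simplify = FALSE)
    split_of <- function(tr, q) {
      kept <- ape::keep.tip(tr, q)
      kept$edge.length <- rep(1, nrow(kept$edge))
      d <- ape::cophenetic.phylo(kept)[q, q]
      s <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
      if (sum(s == min(s)) == 1) which.min(s) else 0L
    }
    mean(vapply(quartets, function(q) split_of(t1, q) != split_of(t2, q),
                logical(1)))
  }

  t1 <- ape::read.tree(text = "((a,b),((c,d),e));")
  expect_equal(quartet_distance(t1, t1), 0)

  set.seed(609)
  for (i in 1:10) {
    ta <- ape::rtree(5)
    tb <- ape::rtree(5)
    expect_equal(quartet_distance(ta, tb), qd_brute(ta, tb))
  }
  for (i in 1:5) {
    ta <- ape::rtree(7)
    tb <- ape::rtree(7)
    expect_equal(quartet_distance(ta, tb), qd_brute(ta, tb))
    expect_equal(quartet_distance(ta, tb), quartet_distance(tb, ta))
  }
})

test_that("random resolved tree pairs agree on about a third of quartets", {
  set.seed(610)
  vals <- replicate(100, {
    quartet_distance(ape::rtree(12), ape::rtree(12))
  })
  expect_true(all(vals >= 0 & vals <= 1))
  agree <- 1 - mean(vals)
  expect_gt(agree, 0.25)
  expect_lt(agree, 0.42)
})
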