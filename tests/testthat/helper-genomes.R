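# Shared fixtures and random-genome helpers for the suite.

fx <- fixtures()

random_pair <- function(n, p_marker = 0.8) {
  u <- make_universe(letters[seq_len(n)])
  list(u = u, A = random_genome(u, p_marker), B = random_genome(u, p_marker))
}

# a relaxed genome: random whole-marker genome with random lone extremities
# knocked out
random_relaxed <- function(u, p_marker = 0.8, p_knock = 0.2) {
  g <- random_genome(u, p_marker)
  adj <- g$adj
  for (x in which(adj > 0L)) {
    if (stats::runif(1) < p_knock) {
      z <- adj[x]
      adj[x] <- 0L
      if (z != x) adj[z] <- z
    }
  }
  new_genome(u, adj)
}

expect_genome_equal <- function(a, b) {
  expect_identical(a$adj, b$adj)
  expect_identical(a$universe$markers, b$universe$markers)
}
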