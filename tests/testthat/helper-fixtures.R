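# Shared fixtures: random quadruples/similarity matrices, an independent
# pair-counting ARI oracle, and an exhaustive set-partition enumerator.

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

rand_quadruples <- function(m, seed = 42, min_cell = 1L, max_cell = 50L) {
  with_seed_local(seed, data.frame(
    a = sample(min_cell:max_cell, m, replace = TRUE),
    b = sample(min_cell:max_cell, m, replace = TRUE),
    c = sample(min_cell:max_cell, m, replace = TRUE),
    d = sample(min_cell:max_cell, m, replace = TRUE)
  ))
}

# symmetric random similarity matrix with dominant diagonal
rand_simmat <- function(p, seed = 42) {
  set.seed(seed)
  m <- matrix(stats::runif(p * p), p, p)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# all set partitions of n items as restricted-growth label vectors
all_partitions <- function(n) {
  grow <- function(labels) {
    if (length(labels) == n) return(list(labels))
    k <- max(labels)
    out <- list()
    for (nxt in seq_len(k + 1L)) out <- c(out, grow(c(labels, nxt)))
    out
  }
  grow(1L)
}

# independent ARI oracle: enumerate all item pairs and count agreements
ari_pair_oracle <- function(l1, l2) {
  n <- length(l1)
  stopifnot(length(l2) == n)
  idx <- utils::combn(n, 2)
  same1 <- l1[idx[1, ]] == l1[idx[2, ]]
  same2 <- l2[idx[1, ]] == l2[idx[2, ]]
  a <- sum(same1 & same2)
  b <- sum(same1 & !same2)
  c <- sum(!same1 & same2)
  npairs <- ncol(idx)
  expected <- (a + b) * (a + c) / npairs
  maximum <- (2 * a + b + c) / 2
  if (abs(maximum - expected) < 1e-12) return(1)
  (a - expected) / (maximum - expected)
}
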