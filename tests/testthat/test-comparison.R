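test_that("correlation matrix matches a hand-computed Pearson r", {
  v <- cbind(x = c(1, 2, 4), y = c(2, 1, 5))
  res <- correlation_matrix(v)
  # textbook sum formula as the oracle
  x <- v[, 1]; y <- v[, 2]; n <- 3
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(res$matrix["x", "y"], r)
  expect_equal(res$matrix, t(res$matrix))
  expect_equal(unname(diag(res$matrix)), c(1, 1))
  expect_error(correlation_matrix(v[1:2, ]), "at least 3")
})

test_that("constant and mostly-undefined columns are dropped with reasons", {
  set.seed(1)
  v <- cbind(ok = rnorm(100), flat = rep(2, 100), holey = rnorm(100))
  v[1:10, "holey"] <- NA
  res <- correlation_matrix(v)
  expect_equal(res$kept, "ok")
  expect_setequal(res$dropped$key, c("flat", "holey"))
  expect_equal(res$dropped$reason[res$dropped$key == "flat"], "zero_variance")
  expect_equal(res$dropped$reason[res$dropped$key == "holey"], "undefined_values")
})

test_that("correlation is invariant to affine rescaling of a column", {
  set.seed(2)
  v <- cbind(a = rnorm(50), b = rnorm(50))
  v2 <- cbind(a = 3 * v[, "a"] - 7, b = v[, "b"])
  expect_equal(correlation_matrix(v)$matrix["a", "b"],
               correlation_matrix(v2)$matrix["a", "b"])
})

test_that("affine-identical coefficient pairs correlate to exactly 1", {
  q <- sample_quadruples(.3, .5, n = 200, trials = 1000, seed = 6)
  res <- correlation_matrix(evaluate_trials(q))
  for (pr in list(c("sokal_michener", "hamann"),
                  c("rogot_goldberg", "scott"),
                  c("gower_legendre", "sokal_sneath2"),
                  c("kulczynski2", "johnson"),
                  c("kulczynski2", "mcconnaughey"),
                  c("baroni_urbani_buser1", "baroni_urbani_buser2"),
                  c("gleason", "van_der_maarel"))) {
    expect_lt(abs(res$matrix[pr[1], pr[2]] - 1), 1e-10)
  }
})

test_that("partition ARI is 1 for identical and relabeled partitions", {
  p1 <- c(a = 1, b = 1, c = 2, d = 2, e = 3)
  expect_equal(partition_ari(p1, p1), 1)
  relab <- c(a = 3, b = 3, c = 1, d = 1, e = 2)
  expect_equal(partition_ari(p1, relab), 1)
  # order of the named items must not matter
  expect_equal(partition_ari(p1, relab[c(4, 2, 1, 5, 3)]), 1)
  expect_error(partition_ari(p1, c(a = 1, b = 2, x = 1, y = 2, z = 3)),
               "label set")
})

test_that("crossed partitions give the hand-derived negative ARI", {
  p1 <- c(i1 = 1, i2 = 1, i3 = 2, i4 = 2)
  p2 <- c(i1 = 1, i2 = 2, i3 = 1, i4 = 2)
  # all 6 item pairs: no pair co-clusters in both, 2 pairs co-cluster in
  # each partition alone; the adjusted formula gives -1/2
  expect_equal(partition_ari(p1, p2), -0.5)
})

test_that("partition ARI agrees with exhaustive pair counting oracles", {
  parts <- all_partitions(5)
  items <- letters[1:5]
  for (i in seq_along(parts)) {
    for (j in seq(i, length(parts))) {
      l1 <- stats::setNames(parts[[i]], items)
      l2 <- stats::setNames(parts[[j]], items)
      got <- partition_ari(l1, l2)
      expect_equal(got, ari_pair_oracle(parts[[i]], parts[[j]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("partition ARI matches the independent mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:20) {
    l1 <- stats::setNames(sample(1:3, 12, replace = TRUE), letters[1:12])
    l2 <- stats::setNames(sample(1:3, 12, replace = TRUE), letters[1:12])
    expect_equal(partition_ari(l1, l2),
                 mclust::adjustedRandIndex(l1, l2[names(l1)]),
                 tolerance = 1e-12)
  }
})

test_that("pair-count ARI coefficient agrees with partition ARI on label vectors", {
  # the registry's adjusted-Rand coefficient evaluates the same quantity as
  # the partition-agreement ARI when the 2x2 table is the cross-tabulation
  # of two binary cluster labelings
  set.seed(4)
  for (i in 1:10) {
    x1 <- rbinom(30, 1, .5)
    x2 <- rbinom(30, 1, .5)
    if (length(unique(x1)) < 2 || length(unique(x2)) < 2) next
    q <- count_quadruple(x1, x2)
    nm <- paste0("o", 1:30)
    expect_equal(evaluate_coefficient("ari", q),
                 partition_ari(stats::setNames(x1, nm), stats::setNames(x2, nm)),
                 tolerance = 1e-12)
  }
})

test_that("ari_matrix is symmetric with unit diagonal", {
  ps <- list(
    one = c(a = 1, b = 1, c = 2, d = 2),
    two = c(a = 1, b = 1, c = 2, d = 2),
    three = c(a = 1, b = 2, c = 1, d = 2)
  )
  m <- ari_matrix(ps)
  expect_equal(m["one", "two"], 1)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
})

test_that("co-membership counts and threshold subsets work", {
  ps <- list(
    p1 = c(x = 1, y = 1, z = 2, w = 2),
    p2 = c(x = 1, y = 1, z = 1, w = 2),
    p3 = c(x = 1, y = 1, z = 2, w = 2)
  )
  rep3 <- co_membership_stability(ps)
  expect_equal(rep3$counts["x", "y"], 3L)
  expect_equal(rep3$counts["x", "z"], 1L)
  expect_equal(unname(diag(rep3$counts)), rep(3L, 4))
  expect_equal(rep3$subsets, list(c("x", "y")))
  # at threshold 2: x-y co-cluster 3 times, z-w twice, x-z/y-z only once
  rep2 <- co_membership_stability(ps, threshold = 2)
  expect_true(any(vapply(rep2$subsets, setequal, TRUE, c("x", "y"))))
  expect_true(any(vapply(rep2$subsets, setequal, TRUE, c("z", "w"))))
  expect_equal(stable_subset_of(rep3, "x"), c("x", "y"))
  expect_equal(stable_subset_of(rep3, "w"), "w")
})

test_that("exemplar table reports requested pairs and flags dropped keys", {
  q1 <- sample_quadruples(.1, .1, n = 500, trials = 500, seed = 8)
  q2 <- sample_quadruples(.5, .7, n = 500, trials = 500, seed = 9)
  res <- list("[.1,.1]" = correlation_matrix(evaluate_trials(q1)),
              "[.5,.7]" = correlation_matrix(evaluate_trials(q2)))
  tab <- exemplar_correlation_table(res, pairs = list(c("phi", "jaccard")))
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab[["phi-jaccard"]][1],
               res[[1]]$matrix["phi", "jaccard"])
  expect_error(
    exemplar_correlation_table(res, pairs = list(c("phi", "goodman_kruskal1"))),
    "goodman_kruskal1")
})
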