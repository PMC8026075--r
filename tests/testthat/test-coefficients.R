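test_that("registry has 71 uniquely identified coefficients with families", {
  meta <- coefficient_metadata()
  expect_equal(nrow(meta), 71L)
  expect_false(anyDuplicated(meta$key) > 0)
  expect_equal(sort(meta$catalog_id), 1:71)
  expect_equal(sum(meta$family == "cooccurrence_no_d"), 18L)
  expect_false(meta$uses_negative_matches[meta$key == "jaccard"])
  expect_true(all(meta$family[meta$key %in% c("rand", "ari")] == "pair_counting"))
})

test_that("direct substitution matches hand-computed values", {
  q <- quadruple(2, 1, 1, 6)
  expect_equal(evaluate_coefficient("jaccard", q), 0.5)
  expect_equal(evaluate_coefficient("sokal_michener", q), 0.8)
  expect_equal(evaluate_coefficient("hamann", q), 0.6)
  expect_equal(evaluate_coefficient("russell_rao", q), 0.2)
  expect_equal(evaluate_coefficient("kulczynski2", q), 2 / 3)
  expect_equal(evaluate_coefficient("johnson", q), 4 / 3)
  expect_error(evaluate_coefficient("nope", q), "unknown coefficient")
})

test_that("independence and symmetry cases come out right", {
  v <- evaluate_all(quadruple(1, 1, 1, 1))
  expect_equal(v[["phi"]], 0)
  expect_equal(v[["jaccard"]], 1 / 3)
  expect_equal(v[["sokal_michener"]], 0.5)
  expect_equal(v[["hamann"]], 0)
  expect_equal(v[["odds_ratio"]], 1)
  expect_equal(v[["yule_q"]], 0)
})

test_that("undefined values propagate as NA, not errors", {
  v <- evaluate_all(quadruple(0, 0, 0, 4))
  expect_true(is.na(v[["jaccard"]]))
  expect_equal(v[["sokal_michener"]], 1)
  q <- quadruple(3, 0, 2, 5)  # bc = 0
  expect_true(is.na(evaluate_coefficient("odds_ratio", q)))
  expect_equal(odds_ratio(q, haldane = TRUE), (3.5 * 5.5) / (0.5 * 2.5))
  # tarantula undefined when c(a+b) = 0
  expect_true(is.na(evaluate_coefficient("tarantula", quadruple(2, 1, 0, 3))))
})

test_that("coefficients with cell-sum denominators are total on positive cells", {
  grid <- expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5)
  m <- evaluate_trials(grid)
  total_keys <- c("dice1", "dice2", "jaccard", "sw_jaccard", "gleason",
                  "kulczynski1", "sokal_sneath1", "van_der_maarel", "ct4",
                  "russell_rao", "ct3", "sokal_michener", "rogers_tanimoto",
                  "sokal_sneath2", "sokal_sneath3", "faith", "gower_legendre",
                  "austin_colwell", "ct1", "hamann", "michael", "dispersion",
                  "ct5", "goodman_kruskal2", "ct2", "hawkins_dotson",
                  "rogot_goldberg", "harris_lahey", "phi", "yule_q")
  expect_false(anyNA(m[, total_keys]))
})

test_that("Goodman-Kruskal I is zero exactly when tau1 equals tau2", {
  # brute-force enumeration of all quadruples with n <= 12
  grid <- expand.grid(a = 0:12, b = 0:12, c = 0:12, d = 0:12)
  grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= 12, ]
  tau1 <- with(grid, pmax(a, b) + pmax(c, d) + pmax(a, c) + pmax(b, d))
  tau2 <- with(grid, pmax(a + c, b + d) + pmax(a + b, c + d))
  v <- evaluate_trials(grid)[, "goodman_kruskal1"]
  ok <- !is.na(v)
  expect_true(all(tau1 >= tau2))
  expect_equal(v[ok] == 0, (tau1 == tau2)[ok])
})

test_that("affine-identity coefficient pairs hold on every quadruple", {
  quads <- rand_quadruples(300, seed = 42)
  m <- evaluate_trials(quads)
  tol <- 1e-12
  expect_equal(m[, "hamann"], 2 * m[, "sokal_michener"] - 1, tolerance = tol)
  expect_equal(m[, "scott"], 2 * m[, "rogot_goldberg"] - 1, tolerance = tol)
  expect_equal(m[, "van_der_maarel"], 2 * m[, "gleason"] - 1, tolerance = tol)
  expect_equal(m[, "johnson"], 2 * m[, "kulczynski2"], tolerance = tol)
  expect_equal(m[, "mcconnaughey"], m[, "johnson"] - 1, tolerance = tol)
  expect_equal(m[, "sokal_sneath2"], m[, "gower_legendre"], tolerance = tol)
  expect_equal(m[, "baroni_urbani_buser2"],
               2 * m[, "baroni_urbani_buser1"] - 1, tolerance = tol)
})

test_that("bounded coefficients respect their ranges", {
  quads <- rand_quadruples(500, seed = 7, min_cell = 0, max_cell = 30)
  quads <- quads[rowSums(quads) > 0, ]
  m <- evaluate_trials(quads)
  in_range <- function(key, lo, hi) {
    v <- m[, key]
    v <- v[!is.na(v)]
    all(v >= lo - 1e-12 & v <= hi + 1e-12)
  }
  for (key in c("jaccard", "gleason", "sokal_michener", "russell_rao")) {
    expect_true(in_range(key, 0, 1), label = key)
  }
  for (key in c("phi", "hamann", "yule_q", "cohen")) {
    expect_true(in_range(key, -1, 1), label = key)
  }
})

test_that("symmetric coefficients are invariant to swapping b and c", {
  quads <- rand_quadruples(200, seed = 9)
  swapped <- data.frame(a = quads$a, b = quads$c, c = quads$b, d = quads$d)
  m1 <- evaluate_trials(quads)
  m2 <- evaluate_trials(swapped)
  for (key in c("jaccard", "phi", "sokal_michener", "yule_q", "rand", "ari",
                "kulczynski2", "hamann", "mountford", "michael")) {
    expect_equal(m1[, key], m2[, key], tolerance = 1e-12, label = key)
  }
})

test_that("perfect agreement quadruples reach the similarity ceiling", {
  quads <- data.frame(a = c(1, 5, 20), b = 0, c = 0, d = c(1, 3, 40))
  m <- evaluate_trials(quads)
  for (key in c("jaccard", "sokal_michener", "phi", "yule_q")) {
    expect_equal(unname(m[, key]), rep(1, 3), label = key)
  }
})

test_that("Loevinger's H variants and base-rate override behave", {
  q <- quadruple(20, 10, 170, 1800)
  # printed form with observed margins: pi1 = 30/2000, pi2 = 190/2000
  n <- 2000
  expect_equal(loevinger_h(q), 1 - 10 / (n * (30 / n) * (190 / n)))
  expect_equal(loevinger_h(q, variant = "guttman"),
               1 - 10 / (n * (30 / n) * (1 - 190 / n)))
  expect_equal(loevinger_h(q, base_rates = c(.1, .1)),
               1 - 10 / (n * .1 * .1))
  # the rarer attribute's mismatches are the Guttman errors
  q2 <- quadruple(20, 170, 10, 1800)
  expect_equal(loevinger_h(q2), loevinger_h(q))
})

test_that("trial evaluation is vectorised and labeled", {
  quads <- rand_quadruples(10)
  m <- evaluate_trials(quads)
  expect_equal(dim(m), c(10L, 71L))
  expect_equal(colnames(m), coefficient_keys())
  one <- evaluate_all(quadruple(quads$a[3], quads$b[3], quads$c[3], quads$d[3]))
  expect_equal(unname(m[3, ]), unname(one))
})

test_that("apply_coefficient builds a labeled attribute similarity matrix", {
  set.seed(5)
  x <- matrix(rbinom(60, 1, .5), 20, 3,
              dimnames = list(NULL, c("i1", "i2", "i3")))
  s <- apply_coefficient(x, "jaccard")
  expect_equal(dim(s), c(3L, 3L))
  expect_equal(s["i1", "i2"],
               evaluate_coefficient("jaccard", count_quadruple(x[, 1], x[, 2])))
  expect_equal(s, t(s))
  expect_error(apply_coefficient(matrix(c(0, 2), 1), "jaccard"), "binary")
})
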