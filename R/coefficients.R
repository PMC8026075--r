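# Registry of 71 binary similarity coefficients on the quadruple (a,b,c,d).
#
# Every formula is implemented as a vectorised function of the four count
# vectors. Division by zero, logarithms of non-positive arguments and other
# out-of-domain evaluations return NA_real_ (a propagating "undefined"
# sentinel) instead of raising: downstream correlation handles missing values
# pairwise. Shared intermediates (margins, ad-bc, tau1/tau2, pair counts,
# chi-square) follow the standard conventions for 2x2 similarity measures.

safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

safe_log <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x > 0
  out[ok] <- log(x[ok])
  out
}

derived <- function(a, b, c, d) {
  n <- a + b + c + d
  p1 <- a + b   # ones of attribute 1
  p2 <- a + c   # ones of attribute 2
  q1 <- c + d
  q2 <- b + d
  list(
    n = n, p1 = p1, p2 = p2, q1 = q1, q2 = q2,
    adbc = a * d - b * c,
    prod4 = p1 * p2 * q1 * q2,
    tau1 = pmax(a, b) + pmax(c, d) + pmax(a, c) + pmax(b, d),
    tau2 = pmax(p2, q2) + pmax(p1, q1)
  )
}

# chi-square statistic of the 2x2 table; NA when any margin is zero
chi_square <- function(a, b, c, d) {
  dv <- derived(a, b, c, d)
  safe_div(dv$n * dv$adbc^2, dv$prod4)
}

# pair counts over the N = n(n-1)/2 observation pairs: Apair co-assigned by
# both binary "partitions", Bpair/Cpair together in one only, Dpair split in
# both. Exact in double precision for n up to ~2e6.
pair_counts <- function(a, b, c, d) {
  n <- a + b + c + d
  N <- n * (n - 1) / 2
  B <- a * b + c * d
  C <- a * c + b * d
  D <- a * d + b * c
  list(N = N, A = N - B - C - D, B = B, C = C, D = D)
}

coef_def <- function(key, label, id, family, uses_d, fun, lo = NA_real_, hi = NA_real_) {
  list(key = key, label = label, catalog_id = id, family = family,
       uses_negative_matches = uses_d, fun = fun, lo = lo, hi = hi)
}

.registry <- list(
  coef_def("dice1", "Dice I", 1L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, a + b), 0, 1),
  coef_def("dice2", "Dice II", 2L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, a + c), 0, 1),
  coef_def("jaccard", "Jaccard", 3L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, a + b + c), 0, 1),
  coef_def("sw_jaccard", "SWJaccard", 4L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(3 * a, 3 * a + b + c), 0, 1),
  coef_def("gleason", "Gleason", 5L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(2 * a, 2 * a + b + c), 0, 1),
  coef_def("kulczynski1", "Kulczynski I", 6L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, b + c)),
  coef_def("kulczynski2", "Kulczynski II", 7L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) 0.5 * (safe_div(a, a + b) + safe_div(a, a + c)), 0, 1),
  coef_def("driver_kroeber", "Driver and Kroeber", 8L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, sqrt((a + b) * (a + c))), 0, 1),
  coef_def("braun_blanquet", "Braun-Blanquet", 9L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, pmax(a + b, a + c)), 0, 1),
  coef_def("simpson", "Simpson", 10L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, pmin(a + b, a + c)), 0, 1),
  coef_def("sorgenfrei", "Sorgenfrei", 11L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a^2, (a + b) * (a + c)), 0, 1),
  coef_def("mountford", "Mountford", 12L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(2 * a, a * b + a * c + 2 * b * c)),
  coef_def("fager_mcgowan", "Fager and McGowan", 13L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) {
             safe_div(a, sqrt((a + b) * (a + c))) -
               0.5 * safe_div(1, sqrt(pmax(a + b, a + c)))
           }),
  coef_def("sokal_sneath1", "Sokal and Sneath I", 14L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, a + 2 * b + 2 * c), 0, 1),
  coef_def("mcconnaughey", "McConnaughey", 15L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a^2 - b * c, (a + b) * (a + c)), -1, 1),
  coef_def("johnson", "Johnson", 16L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(a, a + b) + safe_div(a, a + c), 0, 2),
  coef_def("van_der_maarel", "Van der Maarel", 17L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(2 * a - b - c, 2 * a + b + c), -1, 1),
  coef_def("ct4", "Consonni and Todeschini IV", 18L, "cooccurrence_no_d", FALSE,
           function(a, b, c, d) safe_div(log(1 + a), log(1 + a + b + c)), 0, 1),
  coef_def("russell_rao", "Russell and Rao", 19L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) safe_div(a, a + b + c + d), 0, 1),
  coef_def("ct3", "Consonni and Todeschini III", 20L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) log(1 + a) / log(1 + a + b + c + d), 0, 1),
  coef_def("sokal_michener", "Sokal and Michener", 21L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) (a + d) / (a + b + c + d), 0, 1),
  coef_def("rogers_tanimoto", "Rogers and Tanimoto", 22L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) (a + d) / (a + b + c + d + b + c), 0, 1),
  coef_def("sokal_sneath2", "Sokal and Sneath II", 23L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) 2 * (a + d) / (a + b + c + d + a + d), 0, 1),
  coef_def("sokal_sneath3", "Sokal and Sneath III", 24L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) safe_div(a + d, b + c)),
  coef_def("faith", "Faith", 25L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) (a + d / 2) / (a + b + c + d), 0, 1),
  coef_def("gower_legendre", "Gower and Legendre", 26L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) safe_div(a + d, a + d + (b + c) / 2), 0, 1),
  coef_def("gower", "Gower", 27L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) {
             dv <- derived(a, b, c, d)
             safe_div(a + d, sqrt(dv$prod4))
           }),
  coef_def("austin_colwell", "Austin and Colwell", 28L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) (2 / pi) * asin(sqrt((a + d) / (a + b + c + d))), 0, 1),
  coef_def("ct1", "Consonni and Todeschini I", 29L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) log(1 + a + d) / log(1 + a + b + c + d), 0, 1),
  coef_def("hamann", "Hamann", 30L, "cooccurrence_with_d", TRUE,
           function(a, b, c, d) (a + d - b - c) / (a + b + c + d), -1, 1),
  coef_def("peirce1", "Peirce I", 31L, "association", TRUE,
           function(a, b, c, d) safe_div(a * d - b * c, (a + b) * (c + d)), -1, 1),
  coef_def("peirce2", "Peirce II", 32L, "association", TRUE,
           function(a, b, c, d) safe_div(a * d - b * c, (a + c) * (b + d)), -1, 1),
  coef_def("yule_q", "Yule's Q", 33L, "association", TRUE,
           function(a, b, c, d) safe_div(a * d - b * c, a * d + b * c), -1, 1),
  coef_def("yule_w", "Yule's W", 34L, "association", TRUE,
           function(a, b, c, d) {
             safe_div(sqrt(a * d) - sqrt(b * c), sqrt(a * d) + sqrt(b * c))
           }, -1, 1),
  coef_def("pearson1", "Pearson I", 35L, "chi_square_type", TRUE,
           function(a, b, c, d) chi_square(a, b, c, d)),
  coef_def("pearson2", "Pearson II", 36L, "chi_square_type", TRUE,
           function(a, b, c, d) {
             x2 <- chi_square(a, b, c, d)
             sqrt(x2 / (a + b + c + d + x2))
           }, 0, 1),
  coef_def("phi", "Phi", 37L, "association", TRUE,
           function(a, b, c, d) {
             dv <- derived(a, b, c, d)
             safe_div(dv$adbc, sqrt(dv$prod4))
           }, -1, 1),
  coef_def("michael", "Michael", 38L, "association", TRUE,
           function(a, b, c, d) {
             safe_div(4 * (a * d - b * c), (a + d)^2 + (b + c)^2)
           }, -1, 1),
  coef_def("cole1", "Cole I", 39L, "association", TRUE,
           function(a, b, c, d) safe_div(a * d - b * c, (a + c) * (c + d))),
  coef_def("cole2", "Cole II", 40L, "association", TRUE,
           function(a, b, c, d) safe_div(a * d - b * c, (a + b) * (b + d))),
  coef_def("cohen", "Cohen", 41L, "association", TRUE,
           function(a, b, c, d) {
             safe_div(2 * (a * d - b * c), (a + b) * (b + d) + (a + c) * (c + d))
           }, -1, 1),
  coef_def("maxwell_pilliner", "Maxwell and Pilliner", 42L, "association", TRUE,
           function(a, b, c, d) {
             safe_div(2 * (a * d - b * c), (a + b) * (c + d) + (a + c) * (b + d))
           }, -1, 1),
  coef_def("dennis", "Dennis", 43L, "association", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             safe_div(a * d - b * c, sqrt(n * (a + b) * (a + c)))
           }),
  coef_def("dispersion", "Dispersion", 44L, "association", TRUE,
           function(a, b, c, d) (a * d - b * c) / (a + b + c + d)^2, -0.25, 0.25),
  coef_def("ct5", "Consonni and Todeschini V", 45L, "association", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             (log(1 + a * d) - log(1 + b * c)) / log(1 + n^2 / 4)
           }, -1, 1),
  coef_def("stiles", "Stiles", 46L, "chi_square_type", TRUE,
           function(a, b, c, d) {
             dv <- derived(a, b, c, d)
             arg <- safe_div(dv$n * (abs(dv$adbc) - dv$n / 2)^2, dv$prod4)
             safe_log(arg) / log(10)
           }),
  coef_def("scott", "Scott", 47L, "association", TRUE,
           function(a, b, c, d) {
             safe_div(4 * a * d - (b + c)^2, (2 * a + b + c) * (2 * d + b + c))
           }, -1, 1),
  coef_def("tetrachoric", "Tetrachoric", 48L, "association", TRUE,
           function(a, b, c, d) {
             ad <- a * d
             bc <- b * c
             out <- cos(pi / (1 + sqrt(safe_div(ad, bc))))
             out[bc == 0 & ad > 0] <- 1   # limit of the approximation
             out[bc == 0 & ad == 0] <- NA_real_
             out
           }, -1, 1),
  coef_def("odds_ratio", "Odds Ratio", 49L, "association", TRUE,
           function(a, b, c, d) safe_div(a * d, b * c)),
  coef_def("rand", "Rand", 50L, "pair_counting", TRUE,
           function(a, b, c, d) {
             pc <- pair_counts(a, b, c, d)
             safe_div(pc$A + pc$D, pc$N)
           }, 0, 1),
  coef_def("ari", "ARI", 51L, "pair_counting", TRUE,
           function(a, b, c, d) {
             pc <- pair_counts(a, b, c, d)
             ex <- (pc$A + pc$B) * (pc$A + pc$C) + (pc$C + pc$D) * (pc$B + pc$D)
             safe_div(pc$N * (pc$A + pc$D) - ex, pc$N^2 - ex)
           }),
  coef_def("loevinger_h", "Loevinger's H", 52L, "other", TRUE,
           function(a, b, c, d) loevinger_h_values(a, b, c, d, variant = "printed")),
  coef_def("sokal_sneath4", "Sokal and Sneath IV", 53L, "other", TRUE,
           function(a, b, c, d) {
             0.25 * (safe_div(a, a + b) + safe_div(a, a + c) +
                       safe_div(d, b + d) + safe_div(d, c + d))
           }, 0, 1),
  coef_def("sokal_sneath5", "Sokal and Sneath V", 54L, "other", TRUE,
           function(a, b, c, d) {
             dv <- derived(a, b, c, d)
             safe_div(a * d, sqrt(dv$prod4))
           }, 0, 1),
  coef_def("rogot_goldberg", "Rogot and Goldberg", 55L, "other", TRUE,
           function(a, b, c, d) {
             safe_div(a, 2 * a + b + c) + safe_div(d, 2 * d + b + c)
           }, 0, 1),
  coef_def("baroni_urbani_buser1", "Baroni-Urbani and Buser I", 56L, "other", TRUE,
           function(a, b, c, d) {
             s <- sqrt(a * d)
             safe_div(s + a, s + a + b + c)
           }, 0, 1),
  coef_def("peirce3", "Peirce III", 57L, "other", TRUE,
           function(a, b, c, d) {
             safe_div(a * b + b * c, a * b + 2 * b * c + c * d)
           }),
  coef_def("hawkins_dotson", "Hawkins and Dotson", 58L, "other", TRUE,
           function(a, b, c, d) {
             0.5 * (safe_div(a, a + b + c) + safe_div(d, b + c + d))
           }, 0, 1),
  coef_def("tarantula", "Tarantula", 59L, "other", TRUE,
           function(a, b, c, d) safe_div(a * (c + d), c * (a + b))),
  coef_def("harris_lahey", "Harris and Lahey", 60L, "other", TRUE,
           function(a, b, c, d) {
             safe_div(a * (2 * d + b + c), 2 * (a + b + c)) +
               safe_div(d * (2 * a + b + c), 2 * (b + c + d))
           }),
  coef_def("forbes1", "Forbes I", 61L, "other", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             safe_div(n * a, (a + b) * (a + c))
           }),
  coef_def("baroni_urbani_buser2", "Baroni-Urbani and Buser II", 62L, "other", TRUE,
           function(a, b, c, d) {
             s <- sqrt(a * d)
             safe_div(s + a - b - c, s + a + b + c)
           }, -1, 1),
  coef_def("fossum", "Fossum", 63L, "other", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             safe_div(n * (a - 0.5)^2, (a + b) * (a + c))
           }),
  coef_def("forbes2", "Forbes II", 64L, "other", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             p1 <- a + b
             p2 <- a + c
             safe_div(n * a - p1 * p2, n * pmin(p1, p2) - p1 * p2)
           }),
  coef_def("eyraud", "Eyraud", 65L, "other", TRUE,
           function(a, b, c, d) {
             dv <- derived(a, b, c, d)
             safe_div(dv$n^2 * (dv$n * a - dv$p1 * dv$p2), dv$prod4)
           }),
  coef_def("tarwid", "Tarwid", 66L, "other", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             p1 <- a + b
             p2 <- a + c
             safe_div(n * a - p1 * p2, n * a + p1 * p2)
           }, -1, 1),
  coef_def("goodman_kruskal1", "Goodman and Kruskal I", 67L, "other", TRUE,
           function(a, b, c, d) {
             dv <- derived(a, b, c, d)
             safe_div(dv$tau1 - dv$tau2, 2 * dv$n - dv$tau2)
           }, 0, 1),
  coef_def("anderberg", "Anderberg", 68L, "other", TRUE,
           function(a, b, c, d) {
             dv <- derived(a, b, c, d)
             (dv$tau1 - dv$tau2) / (2 * dv$n)
           }, 0, 1),
  coef_def("goodman_kruskal2", "Goodman and Kruskal II", 69L, "other", TRUE,
           function(a, b, c, d) {
             m <- 2 * pmin(a, d)
             safe_div(m - b - c, m + b + c)
           }, -1, 1),
  coef_def("gilbert_wells", "Gilbert and Wells", 70L, "other", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             safe_log(safe_div(n * a, (a + b) * (a + c)))
           }),
  coef_def("ct2", "Consonni and Todeschini II", 71L, "other", TRUE,
           function(a, b, c, d) {
             n <- a + b + c + d
             (log(1 + n) - log(1 + b + c)) / log(1 + n)
           }, 0, 1)
)
names(.registry) <- vapply(.registry, `[[`, "", "key")

#' Metadata for the 71 registered similarity coefficients
#'
#' Families follow the usual narrative grouping: 18 co-occurrence coefficients
#' that ignore negative matches, co-occurrence coefficients carrying a + d,
#' association coefficients built on ad - bc, chi-square-type measures,
#' pair-counting indices (Rand, adjusted Rand) and assorted others.
#'
#' @return A data frame with one row per coefficient: \code{key},
#'   \code{label}, \code{catalog_id}, \code{family},
#'   \code{uses_negative_matches}, and optional range hints \code{lo}, \code{hi}.
#' @export
coefficient_metadata <- function() {
  data.frame(
    key = vapply(.registry, `[[`, "", "key"),
    label = vapply(.registry, `[[`, "", "label"),
    catalog_id = vapply(.registry, `[[`, 0L, "catalog_id"),
    family = vapply(.registry, `[[`, "", "family"),
    uses_negative_matches = vapply(.registry, `[[`, TRUE, "uses_negative_matches"),
    lo = vapply(.registry, `[[`, 0, "lo"),
    hi = vapply(.registry, `[[`, 0, "hi"),
    row.names = NULL
  )
}

#' Coefficient keys in registry order
#' @return Character vector of the 71 keys.
#' @export
coefficient_keys <- function() names(.registry)

#' Loevinger's H for a contingency quadruple
#'
#' The default \code{"printed"} variant is 1 - b'/(n pi1 pi2) with
#' pi1 <= pi2 the base rates of the two attributes and b' the mismatch count
#' of the smaller-base-rate attribute. The \code{"guttman"} variant divides
#' by n pi1 (1 - pi2), i.e. the expected Guttman errors under independence,
#' as used in Mokken scaling. When the true base rates are known (as in the
#' simulation, where they are design constants) they should be supplied via
#' \code{base_rates}; otherwise the observed margins are used.
#'
#' @param q A \code{\link{quadruple}}.
#' @param variant \code{"printed"} or \code{"guttman"}.
#' @param base_rates Optional length-2 numeric of the two attributes' base
#'   rates, in attribute order.
#' @return A similarity value (1 for error-free Guttman patterns).
#' @export
loevinger_h <- function(q, variant = c("printed", "guttman"), base_rates = NULL) {
  stopifnot(inherits(q, "quadruple"))
  variant <- match.arg(variant)
  loevinger_h_values(q$a, q$b, q$c, q$d, variant,
                     rate1 = base_rates[1], rate2 = base_rates[2])
}

loevinger_h_values <- function(a, b, c, d, variant = "printed",
                               rate1 = NULL, rate2 = NULL) {
  n <- a + b + c + d
  if (is.null(rate1) || is.null(rate2) || is.na(rate1) || is.na(rate2)) {
    m1 <- (a + b) / n
    m2 <- (a + c) / n
  } else {
    m1 <- rate1
    m2 <- rate2
  }
  # Guttman errors of the rarer attribute (m1, m2 may be scalar design rates)
  berr <- ifelse(rep_len(m1 <= m2, length(b)), b, c)
  pi1 <- pmin(m1, m2)
  pi2 <- pmax(m1, m2)
  den <- if (variant == "printed") n * pi1 * pi2 else n * pi1 * (1 - pi2)
  1 - safe_div(berr, den)
}

#' Odds ratio of a contingency quadruple
#'
#' Undefined (NA) when bc = 0; with \code{haldane = TRUE} the 0.5 continuity
#' correction is added to every cell first, making the ratio always finite.
#'
#' @param q A \code{\link{quadruple}}.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction.
#' @export
odds_ratio <- function(q, haldane = FALSE) {
  stopifnot(inherits(q, "quadruple"))
  if (haldane) {
    ((q$a + 0.5) * (q$d + 0.5)) / ((q$b + 0.5) * (q$c + 0.5))
  } else {
    safe_div(q$a * q$d, q$b * q$c)
  }
}

as_counts <- function(q) {
  if (inherits(q, "quadruple")) {
    list(a = q$a, b = q$b, c = q$c, d = q$d)
  } else if (is.data.frame(q) && all(c("a", "b", "c", "d") %in% names(q))) {
    # doubles throughout: cell products overflow 32-bit integers at n = 2000
    list(a = as.numeric(q$a), b = as.numeric(q$b),
         c = as.numeric(q$c), d = as.numeric(q$d))
  } else {
    stop("q must be a quadruple or a data frame with columns a, b, c, d",
         call. = FALSE)
  }
}

#' Evaluate one registered coefficient
#'
#' @param key A registry key (see \code{\link{coefficient_keys}}).
#' @param q A \code{\link{quadruple}}, or a data frame of quadruples with
#'   columns \code{a}, \code{b}, \code{c}, \code{d} (vectorised evaluation).
#' @return Numeric value(s); \code{NA} where the formula is undefined.
#' @examples
#' evaluate_coefficient("jaccard", quadruple(2, 1, 1, 6))
#' @export
evaluate_coefficient <- function(key, q) {
  def <- .registry[[key]]
  if (is.null(def)) stop(sprintf("unknown coefficient key '%s'", key), call. = FALSE)
  x <- as_counts(q)
  def$fun(x$a, x$b, x$c, x$d)
}

#' Evaluate all 71 coefficients on one quadruple
#'
#' @param q A \code{\link{quadruple}}.
#' @return Named numeric vector of length 71 in stable registry order, with
#'   \code{NA} for undefined values.
#' @examples
#' evaluate_all(quadruple(1, 1, 1, 1))[c("phi", "jaccard", "hamann")]
#' @export
evaluate_all <- function(q) {
  stopifnot(inherits(q, "quadruple"))
  vapply(.registry, function(def) def$fun(q$a, q$b, q$c, q$d), 0)
}

#' Evaluate all coefficients across a trial set
#'
#' @param quads Data frame of quadruples (columns \code{a}, \code{b},
#'   \code{c}, \code{d}), e.g. one element of \code{\link{generate_trials}}.
#' @return A trials x 71 numeric matrix, columns named by coefficient key,
#'   carrying the base-rate attributes of the input when present.
#' @export
evaluate_trials <- function(quads) {
  x <- as_counts(quads)
  m <- vapply(.registry, function(def) def$fun(x$a, x$b, x$c, x$d),
              numeric(length(x$a)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(.registry)))
  pi1 <- attr(quads, "pi1")
  pi2 <- attr(quads, "pi2")
  if (!is.null(pi1) && !is.null(pi2)) {
    # design base rates are known constants here; use them in Loevinger's H
    m[, "loevinger_h"] <- loevinger_h_values(x$a, x$b, x$c, x$d, "printed",
                                             rate1 = pi1, rate2 = pi2)
  }
  for (at in c("pi1", "pi2", "n")) attr(m, at) <- attr(quads, at)
  m
}

#' Compute an attribute similarity matrix from a binary data matrix
#'
#' Applies a registered coefficient to every pair of columns of a binary
#' observations-by-attributes matrix, the usual first step before clustering
#' attributes.
#'
#' @param x Binary matrix or data frame, rows = observations,
#'   columns = attributes.
#' @param key Coefficient key.
#' @return A p x p \code{\link{similarity_matrix}}-compatible matrix with the
#'   attribute names as dimnames (self-similarity on the diagonal, computed
#'   from the attribute paired with itself).
#' @export
apply_coefficient <- function(x, key) {
  x <- as.matrix(x)
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("x must be a binary (0/1) matrix", call. = FALSE)
  }
  p <- ncol(x)
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("V", seq_len(p))
  out <- matrix(NA_real_, p, p, dimnames = list(labs, labs))
  for (j in seq_len(p)) {
    for (l in j:p) {
      q <- count_quadruple(x[, j], x[, l])
      out[j, l] <- out[l, j] <- evaluate_coefficient(key, q)
    }
  }
  out
}
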