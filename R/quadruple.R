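#' Contingency quadruple of two binary attributes
#'
#' The counts \code{(a, b, c, d)} obtained by cross-tabulating two binary
#' attributes over the same \code{n} observations: \code{a} positive matches
#' (1,1), \code{b} mismatches with only the first attribute present (1,0),
#' \code{c} mismatches with only the second present (0,1), and \code{d}
#' negative matches (0,0). All 71 similarity coefficients in the registry are
#' functions of this quadruple.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return An object of class \code{"quadruple"}: a named list with elements
#'   \code{a}, \code{b}, \code{c}, \code{d} and the derived total \code{n}.
#' @examples
#' quadruple(2, 1, 1, 6)
#' @export
quadruple <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (length(counts) != 4L || anyNA(counts)) {
    stop("a, b, c, d must be single non-missing counts", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("a, b, c, d must be nonnegative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("a + b + c + d must be positive", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = n),
            class = "quadruple")
}

#' @export
print.quadruple <- function(x, ...) {
  cat(sprintf("quadruple (a=%g, b=%g, c=%g, d=%g; n=%g)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Count the contingency quadruple of two binary vectors
#'
#' @param x1,x2 Binary (0/1) vectors of equal length.
#' @return A \code{\link{quadruple}}.
#' @examples
#' count_quadruple(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
count_quadruple <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    stop("x1 and x2 must have equal length", call. = FALSE)
  }
  if (length(x1) < 1L) stop("vectors must have length >= 1", call. = FALSE)
  if (anyNA(x1) || anyNA(x2) || !all(x1 %in% c(0, 1)) || !all(x2 %in% c(0, 1))) {
    stop("x1 and x2 must contain only 0 and 1", call. = FALSE)
  }
  quadruple(a = sum(x1 * x2), b = sum(x1 * (1 - x2)),
            c = sum((1 - x1) * x2), d = sum((1 - x1) * (1 - x2)))
}

#' The fifteen base-rate design cells
#'
#' The base rate of a binary attribute is its marginal probability of a one.
#' The simulation design crosses base-rate pairs (pi1, pi2) with
#' pi1 <= pi2 over the grid {.1, .3, .5, .7, .9}, giving 15 cells.
#'
#' @return A data frame with columns \code{pi1}, \code{pi2} and a display
#'   \code{label} such as \code{"[.1,.3]"}, in the fixed design order.
#' @export
base_rate_pairs <- function() {
  g <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cells <- expand.grid(pi2 = g, pi1 = g)[, c("pi1", "pi2")]
  cells <- cells[cells$pi1 <= cells$pi2, ]
  cells <- cells[order(cells$pi1, cells$pi2), ]
  rownames(cells) <- NULL
  cells$label <- pair_label(cells$pi1, cells$pi2)
  cells
}

pair_label <- function(pi1, pi2) {
  fmt <- function(x) sub("^0", "", sprintf("%.1f", x))
  sprintf("[%s,%s]", fmt(pi1), fmt(pi2))
}

check_base_rate_pair <- function(pi1, pi2) {
  if (!(pi1 > 0 && pi2 > 0 && pi1 < 1 && pi2 < 1)) {
    stop("base rates must lie strictly between 0 and 1", call. = FALSE)
  }
  if (pi1 > pi2) stop("base rates must satisfy pi1 <= pi2", call. = FALSE)
  invisible(NULL)
}

#' Simulation configuration
#'
#' @param pairs Data frame of base-rate pairs with columns \code{pi1},
#'   \code{pi2} (and optionally \code{label}); defaults to the 15-cell design
#'   of \code{\link{base_rate_pairs}}.
#' @param trials Number of Monte-Carlo trials per base-rate pair.
#' @param n Length of the two binary vectors reduced to each quadruple.
#' @param seed Master seed; per-pair child seeds are derived from it so any
#'   subset of pairs reproduces the same quadruples.
#' @param sampler \code{"multinomial"} draws the quadruple directly from its
#'   exact multinomial distribution under independence; \code{"explicit_vectors"}
#'   draws the two Bernoulli vectors and counts them. The two are
#'   distributionally identical; the multinomial path is the fast default.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(pairs = base_rate_pairs(), trials = 100000L,
                              n = 2000L, seed = 1L,
                              sampler = c("multinomial", "explicit_vectors")) {
  sampler <- match.arg(sampler)
  stopifnot(is.data.frame(pairs), all(c("pi1", "pi2") %in% names(pairs)),
            nrow(pairs) >= 1L, trials >= 1L, n >= 4L)
  for (i in seq_len(nrow(pairs))) check_base_rate_pair(pairs$pi1[i], pairs$pi2[i])
  if (is.null(pairs$label)) pairs$label <- pair_label(pairs$pi1, pairs$pi2)
  structure(list(pairs = pairs, trials = as.integer(trials), n = as.integer(n),
                 seed = as.integer(seed), sampler = sampler),
            class = "simulation_config")
}

# Deterministic child seed for pair i; kept below 2^31 - 1.
pair_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(i)) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

#' Draw one contingency quadruple at a base-rate pair
#'
#' Under independence of the two attributes the quadruple of two Bernoulli
#' vectors is exactly multinomial with cell probabilities
#' (pi1 pi2, pi1 (1-pi2), (1-pi1) pi2, (1-pi1)(1-pi2)), so the two sampler
#' modes agree in distribution.
#'
#' @param pi1,pi2 Base rates in (0, 1), pi1 <= pi2.
#' @param n Vector length.
#' @param sampler See \code{\link{simulation_config}}.
#' @param seed Optional seed for this draw.
#' @return A \code{\link{quadruple}}.
#' @export
sample_quadruple <- function(pi1, pi2, n = 2000L,
                             sampler = c("multinomial", "explicit_vectors"),
                             seed = NULL) {
  q <- sample_quadruples(pi1, pi2, n = n, trials = 1L, sampler = sampler,
                         seed = seed)
  quadruple(q$a[1L], q$b[1L], q$c[1L], q$d[1L])
}

#' Draw a batch of contingency quadruples at a base-rate pair
#'
#' @inheritParams sample_quadruple
#' @param trials Number of quadruples to draw.
#' @return A data frame with columns \code{a}, \code{b}, \code{c}, \code{d},
#'   one row per trial.
#' @export
sample_quadruples <- function(pi1, pi2, n = 2000L, trials = 1L,
                              sampler = c("multinomial", "explicit_vectors"),
                              seed = NULL) {
  sampler <- match.arg(sampler)
  check_base_rate_pair(pi1, pi2)
  stopifnot(n >= 4L, trials >= 1L)
  with_seed(seed, {
    if (sampler == "multinomial") {
      pr <- c(pi1 * pi2, pi1 * (1 - pi2), (1 - pi1) * pi2, (1 - pi1) * (1 - pi2))
      m <- stats::rmultinom(trials, size = n, prob = pr)
      data.frame(a = m[1L, ], b = m[2L, ], c = m[3L, ], d = m[4L, ])
    } else {
      a <- b <- cc <- d <- integer(trials)
      for (t in seq_len(trials)) {
        x1 <- stats::rbinom(n, 1L, pi1)
        x2 <- stats::rbinom(n, 1L, pi2)
        a[t] <- sum(x1 & x2)
        b[t] <- sum(x1 & !x2)
        cc[t] <- sum(!x1 & x2)
        d[t] <- n - a[t] - b[t] - cc[t]
      }
      data.frame(a = a, b = b, c = cc, d = d)
    }
  })
}

#' Generate the full trial set for every base-rate pair
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A named list (one element per base-rate pair label) of data frames
#'   with columns \code{a}, \code{b}, \code{c}, \code{d} and attributes
#'   \code{pi1}, \code{pi2}, \code{n}.
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pairs <- config$pairs
  out <- vector("list", nrow(pairs))
  names(out) <- pairs$label
  for (i in seq_len(nrow(pairs))) {
    # the child seed is keyed to the pair's position in the canonical design,
    # not to its position in a possibly subsetted config, when it matches a
    # canonical cell; this keeps any subset run identical to the full run
    canon <- base_rate_pairs()
    hit <- which(abs(canon$pi1 - pairs$pi1[i]) < 1e-12 &
                   abs(canon$pi2 - pairs$pi2[i]) < 1e-12)
    key <- if (length(hit) == 1L) hit else nrow(canon) + i
    q <- sample_quadruples(pairs$pi1[i], pairs$pi2[i], n = config$n,
                           trials = config$trials, sampler = config$sampler,
                           seed = pair_seed(config$seed, key))
    attr(q, "pi1") <- pairs$pi1[i]
    attr(q, "pi2") <- pairs$pi2[i]
    attr(q, "n") <- config$n
    out[[i]] <- q
  }
  out
}
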