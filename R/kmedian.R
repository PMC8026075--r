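# K-median (p-median / PAM-style) partitioning of a similarity matrix by
# multistart fast interchange. The objective maximised is
#   Z = sum_i max_{j in Q} s_ij,   |Q| = K,
# i.e. each attribute contributes its similarity to the most similar
# exemplar. Diagonal entries must be row maxima (ties allowed) so that every
# exemplar is assigned to itself.

#' Validate a labeled similarity matrix
#'
#' @param values Square numeric matrix of pairwise similarities.
#' @param labels Optional attribute labels (defaults to dimnames).
#' @return The matrix with dimnames set, invisibly classed
#'   \code{"similarity_matrix"}.
#' @export
similarity_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square", call. = FALSE)
  if (any(!is.finite(values))) stop("similarity matrix must be finite", call. = FALSE)
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(values)))
  if (length(labels) != nrow(values)) stop("labels length mismatch", call. = FALSE)
  row_max <- apply(values, 1L, max)
  if (any(diag(values) < row_max - 1e-9)) {
    stop("each diagonal entry must be maximal in its row", call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  class(values) <- c("similarity_matrix", "matrix")
  values
}

as_simmat <- function(S) {
  if (inherits(S, "similarity_matrix")) unclass(S) else unclass(similarity_matrix(S))
}

#' K-median objective for an exemplar subset
#'
#' @param S Similarity matrix (see \code{\link{similarity_matrix}}).
#' @param exemplars Integer indices (or labels) of the exemplar subset Q.
#' @return Z, the sum over attributes of the similarity to the nearest
#'   exemplar.
#' @export
kmedian_objective <- function(S, exemplars) {
  S <- as_simmat(S)
  idx <- resolve_indices(S, exemplars)
  if (length(idx) == 0L) stop("exemplar set must be nonempty", call. = FALSE)
  sum(row_max_over(S, idx))
}

resolve_indices <- function(S, x) {
  if (is.character(x)) {
    idx <- match(x, rownames(S))
    if (anyNA(idx)) stop("unknown exemplar label", call. = FALSE)
    idx
  } else {
    x <- as.integer(x)
    if (any(x < 1L | x > nrow(S))) stop("exemplar index out of range", call. = FALSE)
    x
  }
}

row_max_over <- function(S, idx) {
  if (length(idx) == 1L) S[, idx] else do.call(pmax, asplit(S[, idx, drop = FALSE], 2L))
}

new_partition <- function(S, Q) {
  p <- nrow(S)
  sub <- S[, Q, drop = FALSE]
  pos <- max.col(sub, ties.method = "first")  # lowest-index exemplar on ties
  assigned <- Q[pos]
  obj <- sum(S[cbind(seq_len(p), assigned)])
  structure(list(exemplars = Q,
                 assignment = stats::setNames(assigned, rownames(S)),
                 cluster = stats::setNames(match(assigned, Q), rownames(S)),
                 objective = obj,
                 k = length(Q)),
            class = "kmedian_partition")
}

#' @export
print.kmedian_partition <- function(x, ...) {
  cat(sprintf("K-median partition: K=%d, Z=%.6g\n", x$k, x$objective))
  cat("exemplars:", paste(names(x$assignment)[x$exemplars], collapse = ", "), "\n")
  invisible(x)
}

#' Fast-interchange local search for K-median partitioning
#'
#' Starts from K random (or supplied) exemplars, assigns every attribute to
#' its most similar exemplar, then repeatedly evaluates replacing an exemplar
#' with a non-exemplar, accepting any swap that increases Z, until no swap
#' improves. The result is locally optimal with respect to all single
#' exemplar interchanges.
#'
#' @param S Similarity matrix.
#' @param k Number of clusters (exemplars), 1 <= k <= p.
#' @param exemplars Optional initial exemplar indices; random if NULL.
#' @param improvement \code{"first"} accepts the first improving swap found in
#'   the scan and restarts the scan; \code{"best"} takes the best improving
#'   replacement for each removed exemplar.
#' @param eps Strict-improvement threshold guarding against floating-point
#'   cycling.
#' @return A \code{kmedian_partition}: exemplars, per-attribute assignment and
#'   cluster id, and the objective Z.
#' @export
fast_interchange <- function(S, k, exemplars = NULL,
                             improvement = c("first", "best"), eps = 1e-12) {
  improvement <- match.arg(improvement)
  S <- as_simmat(S)
  p <- nrow(S)
  stopifnot(k >= 1L, k <= p)
  Q <- if (is.null(exemplars)) sort(sample.int(p, k)) else sort(resolve_indices(S, exemplars))
  stopifnot(length(Q) == k, !anyDuplicated(Q))
  repeat {
    improved <- FALSE
    for (ri in seq_along(Q)) {
      rest <- Q[-ri]
      rest_max <- if (length(rest)) row_max_over(S, rest) else rep(-Inf, p)
      z_cur <- sum(pmax(rest_max, S[, Q[ri]]))
      cand <- setdiff(seq_len(p), Q)
      if (!length(cand)) next
      z_cand <- colSums(pmax(S[, cand, drop = FALSE], rest_max))
      better <- which(z_cand > z_cur + eps)
      if (length(better)) {
        pick <- if (improvement == "first") better[1L] else better[which.max(z_cand[better])]
        Q[ri] <- cand[pick]
        Q <- sort(Q)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  new_partition(S, Q)
}

#' Multistart K-median partitioning
#'
#' Runs \code{\link{fast_interchange}} from \code{restarts} independent random
#' starts and keeps the best objective; ties are broken in favour of the
#' first solution found. Deterministic given \code{seed}.
#'
#' @inheritParams fast_interchange
#' @param restarts Number of random restarts.
#' @param seed Optional seed for the restart stream.
#' @return The best \code{kmedian_partition} found, with attributes
#'   \code{restarts} and \code{seed}.
#' @export
multistart_kmedian <- function(S, k, restarts = 2000L, seed = NULL,
                               improvement = c("first", "best")) {
  improvement <- match.arg(improvement)
  S <- as_simmat(S)
  stopifnot(restarts >= 1L)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      part <- fast_interchange(S, k, improvement = improvement)
      if (is.null(best) || part$objective > best$objective) best <- part
    }
  })
  attr(best, "restarts") <- restarts
  attr(best, "seed") <- seed
  best
}

#' Exhaustive K-median optimum (test oracle)
#'
#' Enumerates every size-K exemplar subset; intended for small instances as
#' an independent check on the heuristic.
#'
#' @inheritParams fast_interchange
#' @param max_subsets Guard on the number of subsets enumerated.
#' @return The globally optimal \code{kmedian_partition}.
#' @export
brute_force_kmedian <- function(S, k, max_subsets = 1e6) {
  S <- as_simmat(S)
  p <- nrow(S)
  stopifnot(k >= 1L, k <= p)
  if (choose(p, k) > max_subsets) {
    stop("too many exemplar subsets to enumerate", call. = FALSE)
  }
  subsets <- utils::combn(p, k)
  z <- apply(subsets, 2L, function(Q) sum(row_max_over(S, Q)))
  new_partition(S, subsets[, which.max(z)])
}
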