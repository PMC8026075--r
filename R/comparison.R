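# Inter-coefficient correlation matrices with the undefined/zero-variance
# drop rule, Hubert-Arabie adjusted Rand comparison of partitions, and
# co-membership stability of coefficients across base-rate conditions.

#' Inter-coefficient Pearson correlation matrix with drop rule
#'
#' Columns (coefficients) are dropped before correlating when their observed
#' values have zero variance (a constant cannot be correlated with anything)
#' or when more than \code{max_undefined} of their values are undefined.
#' Remaining correlations use pairwise complete observations, so a small
#' fraction of undefined values is harmless; the default tolerance of 0.5%
#' keeps coefficients whose formulas fail only on rare lattice coincidences
#' of the counts while still excluding systematically undefined ones.
#'
#' @param values Trials x coefficients numeric matrix (e.g. from
#'   \code{\link{evaluate_trials}}); columns must be named.
#' @param max_undefined Maximum tolerated fraction of undefined values per
#'   coefficient (default 0.005).
#' @return A list of class \code{"coefficient_correlation"}: \code{kept}
#'   (keys retained), \code{matrix} (k x k Pearson correlations, unit
#'   diagonal) and \code{dropped} (data frame of key and reason,
#'   \code{"zero_variance"} or \code{"undefined_values"}).
#' @export
correlation_matrix <- function(values, max_undefined = 0.005) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have column names", call. = FALSE)
  if (nrow(values) < 3L) stop("need at least 3 trials to correlate", call. = FALSE)
  keys <- colnames(values)
  na_frac <- colMeans(is.na(values))
  rng <- apply(values, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L) return(NA_real_)
    diff(range(v))
  })
  reason <- rep(NA_character_, length(keys))
  reason[!is.na(rng) & rng <= 1e-12] <- "zero_variance"
  reason[na_frac > max_undefined] <- "undefined_values"
  drop <- !is.na(reason)
  kept <- keys[!drop]
  m <- stats::cor(values[, kept, drop = FALSE], use = "pairwise.complete.obs")
  diag(m) <- 1
  structure(list(kept = kept,
                 matrix = m,
                 dropped = data.frame(key = keys[drop], reason = reason[drop],
                                      row.names = NULL)),
            class = "coefficient_correlation")
}

#' @export
print.coefficient_correlation <- function(x, ...) {
  cat(sprintf("coefficient correlation matrix: %d kept, %d dropped\n",
              length(x$kept), nrow(x$dropped)))
  if (nrow(x$dropped)) {
    cat("dropped:", paste(x$dropped$key, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coefficients retained in every correlation result
#'
#' A coefficient dropped at any base-rate pair is excluded globally, so that
#' all per-pair partitions are over a common label set.
#'
#' @param results List of \code{\link{correlation_matrix}} results.
#' @return Character vector of keys kept in every result, in the order of the
#'   first.
#' @export
globally_kept <- function(results) {
  Reduce(intersect, lapply(results, `[[`, "kept"))
}

partition_labels <- function(p) {
  if (inherits(p, "kmedian_partition")) return(p$cluster)
  if (is.null(names(p))) stop("partitions must be named label vectors", call. = FALSE)
  p
}

#' Hubert-Arabie adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions (up
#' to cluster relabeling), approximately 0 under random agreement.
#'
#' @param p1,p2 Partitions over the same items: \code{kmedian_partition}
#'   objects or named cluster-label vectors.
#' @return The ARI.
#' @export
partition_ari <- function(p1, p2) {
  l1 <- partition_labels(p1)
  l2 <- partition_labels(p2)
  if (length(l1) != length(l2) || !setequal(names(l1), names(l2))) {
    stop("partitions must share the same item label set", call. = FALSE)
  }
  l2 <- l2[names(l1)]
  tab <- table(l1, l2)
  npairs <- choose(sum(tab), 2)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / npairs
  maximum <- (si + sj) / 2
  if (abs(maximum - expected) < .Machine$double.eps * npairs) {
    return(1)  # both partitions degenerate and identical in pair structure
  }
  (sij - expected) / (maximum - expected)
}

#' ARI matrix across a set of partitions
#'
#' @param partitions Named list of partitions on a common item set (typically
#'   one two-cluster partition per base-rate pair).
#' @return Symmetric matrix of pairwise \code{\link{partition_ari}} values
#'   with unit diagonal, rows/columns in the input order.
#' @export
ari_matrix <- function(partitions) {
  stopifnot(length(partitions) >= 2L)
  k <- length(partitions)
  labs <- names(partitions)
  if (is.null(labs)) labs <- paste0("P", seq_len(k))
  m <- diag(1, k)
  dimnames(m) <- list(labs, labs)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- partition_ari(partitions[[i]], partitions[[j]])
    }
  }
  m
}

#' Co-membership stability of items across partitions
#'
#' Counts, for every pair of items, in how many partitions the two fall in
#' the same cluster, and extracts the maximal groups whose every internal
#' pair co-clusters in at least \code{threshold} partitions (maximal cliques
#' of the thresholded co-membership graph; only groups of two or more items
#' are reported).
#'
#' @param partitions Named list of partitions over a common item set.
#' @param threshold Minimum number of partitions (default: all of them).
#' @return A list of class \code{"stability_report"}: \code{counts} (items x
#'   items integer matrix, diagonal = number of partitions), \code{subsets}
#'   (list of character vectors, largest first), \code{threshold} and
#'   \code{n_partitions}.
#' @export
co_membership_stability <- function(partitions, threshold = length(partitions)) {
  stopifnot(length(partitions) >= 1L, threshold >= 1L,
            threshold <= length(partitions))
  labs0 <- names(partition_labels(partitions[[1]]))
  counts <- matrix(0L, length(labs0), length(labs0), dimnames = list(labs0, labs0))
  for (p in partitions) {
    cl <- partition_labels(p)
    if (!setequal(names(cl), labs0)) {
      stop("all partitions must share the same item label set", call. = FALSE)
    }
    cl <- cl[labs0]
    counts <- counts + outer(cl, cl, `==`)
  }
  adj <- counts >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g, min = 2L)
  subsets <- lapply(cliques, function(v) sort(names(v)))
  subsets <- subsets[order(-lengths(subsets))]
  structure(list(counts = counts, subsets = subsets, threshold = threshold,
                 n_partitions = length(partitions)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("co-membership stability: %d partitions, threshold %d, %d subsets\n",
              x$n_partitions, x$threshold, length(x$subsets)))
  for (i in seq_along(x$subsets)) {
    cat(sprintf("  subset %d (%d): %s\n", i, length(x$subsets[[i]]),
                paste(x$subsets[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Stable subset containing a given item
#'
#' @param report A \code{\link{co_membership_stability}} result.
#' @param key Item (coefficient) key.
#' @return Character vector of the subset containing \code{key}, or the
#'   singleton \code{key} if it is in no reported subset.
#' @export
stable_subset_of <- function(report, key) {
  hit <- Filter(function(s) key %in% s, report$subsets)
  if (!length(hit)) return(key)
  hit[[which.max(lengths(hit))]]
}

#' Correlations between selected coefficient pairs across base-rate pairs
#'
#' @param results Named list (by base-rate pair label) of
#'   \code{\link{correlation_matrix}} results.
#' @param pairs List of length-2 character vectors of coefficient keys.
#'   Defaults to the exemplar comparisons phi-Jaccard, phi-Sokal-Michener,
#'   Jaccard-Sokal-Michener, phi-Loevinger's H and phi-ARI.
#' @return Data frame: one row per base-rate pair, one column per coefficient
#'   pair (named \code{"key1-key2"}).
#' @export
exemplar_correlation_table <- function(results,
                                       pairs = list(
                                         c("phi", "jaccard"),
                                         c("phi", "sokal_michener"),
                                         c("jaccard", "sokal_michener"),
                                         c("phi", "loevinger_h"),
                                         c("phi", "ari"))) {
  stopifnot(length(results) >= 1L)
  cols <- vapply(pairs, paste, "", collapse = "-")
  out <- data.frame(pair = names(results), row.names = NULL)
  for (j in seq_along(pairs)) {
    ks <- pairs[[j]]
    out[[cols[j]]] <- vapply(results, function(r) {
      miss <- setdiff(ks, r$kept)
      if (length(miss)) {
        stop(sprintf("coefficient '%s' was dropped and cannot be tabulated",
                     miss[1]), call. = FALSE)
      }
      r$matrix[ks[1], ks[2]]
    }, 0)
  }
  out
}
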