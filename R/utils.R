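.datatable.aware <- TRUE
utils::globalVariables(c("pseudobulk_id", "patient", "state", "cell_id",
                         "inc_count", "skip_count", "event_id", ".N", "."))

logit <- function(p) qlogis(p)
logistic <- function(x) plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items.
#' Equals 1 for identical partitions (up to label permutation) and has
#' expectation 0 under random labelings.
#'
#' @param a,b integer or factor vectors of equal length with cluster labels.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stop_if_not(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Silhouette widths from a distance matrix
#'
#' Standard silhouette width s(i) = (b_i - a_i) / max(a_i, b_i) where a_i is
#' the mean distance to the own cluster and b_i the smallest mean distance to
#' any other cluster. Members of singleton clusters get width 0.
#'
#' @param d square symmetric distance matrix.
#' @param labels cluster labels, one per row of `d`.
#' @return Numeric vector of widths in \[-1, 1\].
#' @export
silhouette_widths <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  stop_if_not(length(labels) == n, "labels must match distance matrix size")
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    idx_own <- which(labels == own)
    if (length(idx_own) == 1L) { out[i] <- 0; next }
    a_i <- mean(d[i, setdiff(idx_own, i)])
    b_i <- min(vapply(setdiff(ks, own), function(k) {
      mean(d[i, labels == k])
    }, numeric(1)))
    out[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  out
}

#' Derive a reproducible sub-seed from a base seed
#'
#' Deterministically offsets a base seed into distinct substreams (one per
#' generator or replicate) while keeping the result a valid 32-bit integer.
#'
#' @param seed base integer seed.
#' @param offset integer substream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647L)
}
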