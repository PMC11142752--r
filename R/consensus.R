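#' Consensus k-means clustering of samples
#'
#' Resampling-based consensus clustering on a filtered PSI matrix. Each
#' iteration subsamples `subsample_frac` of the samples, z-scores each event
#' row over the subsample ("AS row wise" normalization), standardizes each
#' sample profile so that Euclidean k-means operates in Pearson-correlation
#' geometry, and runs k-means (`nstart` restarts). Co-clustering frequencies
#' are accumulated into the consensus matrix `M` = co-cluster count /
#' co-sampled count; final labels come from average-linkage hierarchical
#' clustering of `1 - M` cut at `k`.
#'
#' @param x a `PsiMatrix` or a complete events x samples matrix (missing
#'   entries are median-imputed via [impute_psi()]).
#' @param k number of clusters (default 2).
#' @param n_iter resampling iterations (reference setting 1000).
#' @param subsample_frac fraction of samples per iteration (default 0.8).
#' @param seed integer seed.
#' @param nstart k-means restarts per iteration (default 10).
#' @return A `ConsensusResult`: list with `M` (consensus matrix), `labels`,
#'   `silhouette` (widths on distance `1 - M`), `k`, `n_iterations`.
#' @export
consensus_cluster <- function(x, k = 2, n_iter = 1000, subsample_frac = 0.8,
                              seed = 1, nstart = 10) {
  m <- impute_psi(x)
  samples <- colnames(m) %||% paste0("S", seq_len(ncol(m)))
  n <- ncol(m)
  stop_if_not(k >= 2, "k must be >= 2")
  stop_if_not(k <= n, "k must not exceed the number of samples")
  set.seed(seed)

  co_cluster <- matrix(0, n, n)
  co_sampled <- matrix(0, n, n)
  n_sub <- max(k, round(subsample_frac * n))
  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(n, n_sub))
    sub <- m[, idx, drop = FALSE]
    sub <- row_zscore(sub)
    prof <- col_standardize(sub)
    km <- suppressWarnings(
      kmeans(t(prof), centers = k, nstart = nstart, iter.max = 50))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    for (c_ in seq_len(k)) {
      mem <- idx[km$cluster == c_]
      co_cluster[mem, mem] <- co_cluster[mem, mem] + 1
    }
  }
  M <- ifelse(co_sampled > 0, co_cluster / co_sampled, 0)
  diag(M) <- 1
  dimnames(M) <- list(samples, samples)
  hc <- hclust(as.dist(1 - M), method = "average")
  labels <- cutree(hc, k = k)
  sil <- silhouette_widths(1 - M, labels)
  structure(list(M = M, labels = setNames(labels, samples),
                 silhouette = setNames(sil, samples),
                 k = k, n_iterations = n_iter),
            class = "ConsensusResult")
}

row_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0 | is.na(s)] <- 1
  (m - mu) / s
}

# per-column standardization => squared Euclidean distance between columns
# is an affine function of (1 - Pearson correlation)
col_standardize <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  t((t(m) - mu) / s)
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: k=%d, %d samples, %d iterations\n",
              x$k, length(x$labels), x$n_iterations))
  print(table(x$labels))
  invisible(x)
}

#' Select representative samples by silhouette width
#'
#' Ranks samples by silhouette width (computed on distance `1 - M`) and
#' returns the top `n_select` with strictly positive width; fewer are
#' returned (with a warning when none) if not enough are positive.
#'
#' @param result a `ConsensusResult`.
#' @param n_select number of representatives requested (reference 400).
#' @return Character vector of sample ids.
#' @export
select_representatives <- function(result, n_select = 400) {
  sil <- result$silhouette
  pos <- sil[sil > 0]
  if (length(pos) == 0) {
    warning("no samples with positive silhouette width")
    return(character())
  }
  ord <- names(pos)[order(-pos, names(pos))]
  head(ord, n_select)
}

#' Consensus CDF delta-area report over a range of k
#'
#' Transparency diagnostic for choosing k: the area under the consensus-value
#' CDF per k and the relative increase (delta area) from k-1 to k.
#'
#' @param x matrix or `PsiMatrix`.
#' @param ks integer vector of cluster counts (default 2:6).
#' @param ... passed to [consensus_cluster()] (use a reduced `n_iter`).
#' @return data.frame with `k`, `auc`, `delta_area`.
#' @export
consensus_cdf_report <- function(x, ks = 2:6, ...) {
  aucs <- vapply(ks, function(k) {
    res <- consensus_cluster(x, k = k, ...)
    v <- sort(res$M[upper.tri(res$M)])
    cdf <- seq_along(v) / length(v)
    sum(diff(v) * cdf[-length(cdf)])
  }, numeric(1))
  delta <- c(aucs[1], diff(aucs) / aucs[-length(aucs)])
  data.frame(k = ks, auc = aucs, delta_area = delta)
}
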