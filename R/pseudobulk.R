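#' Aggregate single-cell junction counts into cell-state pseudobulks
#'
#' Sums inclusion and skipping counts over all cells sharing a
#' (patient, cellular state) label — the counts are combined before PSI
#' estimation, never averaged per cell — rescuing coverage for splicing
#' quantification in sparse single-cell data.
#'
#' @param counts data.frame with `cell_id`, `event_id`, `inc_count`,
#'   `skip_count` (zero-coverage rows may be omitted).
#' @param annotation data.frame with `cell_id`, `patient`, `state`; must
#'   cover every counted cell.
#' @return list with `counts` (long table keyed by `pseudobulk_id` =
#'   `patient:state`, summed counts) and `pseudobulks` (id, patient, state,
#'   `n_cells` from the annotation).
#' @export
aggregate_pseudobulk <- function(counts, annotation) {
  unknown <- setdiff(unique(counts$cell_id), annotation$cell_id)
  stop_if_not(length(unknown) == 0, "unannotated cell id(s): %s",
              paste(head(unknown, 5), collapse = ", "))
  ann <- data.table::as.data.table(annotation)
  ann[, pseudobulk_id := paste(patient, state, sep = ":")]
  dt <- data.table::as.data.table(counts)
  dt <- merge(dt, ann[, .(cell_id, pseudobulk_id)], by = "cell_id")
  agg <- dt[, .(inc_count = sum(inc_count), skip_count = sum(skip_count)),
            by = .(pseudobulk_id, event_id)]
  data.table::setorder(agg, pseudobulk_id, event_id)
  pbs <- ann[, .(n_cells = .N), by = .(pseudobulk_id, patient, state)]
  data.table::setorder(pbs, pseudobulk_id)
  list(counts = as.data.frame(agg), pseudobulks = as.data.frame(pbs))
}

#' PSI matrix for pseudobulks
#'
#' Convenience wrapper: renames `pseudobulk_id` to `sample_id` and calls
#' [build_psi_matrix()] on the summed counts, so pseudobulk PSI equals the
#' PSI of the summed counts exactly.
#'
#' @param pb result of [aggregate_pseudobulk()].
#' @param events event annotation table.
#' @param min_reads detection threshold.
#' @return A `PsiMatrix` (events x pseudobulks).
#' @export
pseudobulk_psi <- function(pb, events, min_reads = 10) {
  cnt <- pb$counts
  names(cnt)[names(cnt) == "pseudobulk_id"] <- "sample_id"
  build_psi_matrix(cnt, events, min_reads = min_reads,
                   samples = pb$pseudobulks$pseudobulk_id)
}

#' Filter pseudobulks and events by signature detection
#'
#' Drops pseudobulks in which fewer than `min_events` of the signature
#' events are detected, then drops events detected in fewer than
#' `min_pseudobulks` of the remaining pseudobulks. `min_pseudobulks` < 1 is
#' interpreted as a fraction of pseudobulks (scale-aware alternative to the
#' absolute reference thresholds 50 events / 100 pseudobulks).
#'
#' @param x a `PsiMatrix` of pseudobulks.
#' @param signature_events character vector of signature event ids.
#' @param min_events minimum detected signature events per pseudobulk
#'   (reference 50 of 200).
#' @param min_pseudobulks minimum pseudobulks per event (reference 100), or
#'   a fraction in (0,1).
#' @return list with `kept_pseudobulks`, `kept_events`, and the filtered
#'   `matrix` (a `PsiMatrix` restricted to signature events).
#' @export
filter_pseudobulks <- function(x, signature_events, min_events = 50,
                               min_pseudobulks = 100) {
  sig <- intersect(signature_events, x$events)
  stop_if_not(length(sig) > 0, "no signature events present in matrix")
  sub <- subset_psi(x, events = sig)
  det_per_pb <- colSums(sub$detected)
  kept_pb <- sub$samples[det_per_pb >= min_events]
  sub2 <- subset_psi(sub, samples = kept_pb)
  thr <- if (min_pseudobulks < 1) min_pseudobulks * length(kept_pb)
         else min_pseudobulks
  det_per_ev <- rowSums(sub2$detected)
  kept_ev <- sub2$events[det_per_ev >= thr]
  list(kept_pseudobulks = kept_pb, kept_events = kept_ev,
       matrix = subset_psi(sub2, events = kept_ev))
}

#' Uncentered correlation between vectors with pairwise-complete entries
#'
#' \eqn{u(x, y) = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}} over entries
#' where both values are present — the Cluster 3.0 similarity that does not
#' subtract means, so positive scalings of a profile are identical
#' (`u = 1`).
#'
#' @param x,y numeric vectors (may contain `NA`).
#' @return The similarity in \[-1, 1\], or `NA` if undefined (no co-present
#'   entries or a zero-norm vector).
#' @export
uncentered_cor <- function(x, y) {
  stop_if_not(length(x) == length(y), "vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  sx <- sum(x[ok]^2); sy <- sum(y[ok]^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(x[ok] * y[ok]) / sqrt(sx * sy)
}

#' Cluster-3.0-style hierarchical clustering (uncentered correlation,
#' centroid linkage)
#'
#' Agglomerates rows (or columns) of a matrix with distance `1 - u` where
#' `u` is the pairwise-complete uncentered correlation, using centroid
#' linkage as in Cluster 3.0: a merge joins the clusters' centroids (per-
#' coordinate means over member rows, missing values ignored) and distances
#' are recomputed between centroids. Ties are broken by the lowest-index
#' pair and leaf order follows input order within merges, so results are
#' deterministic. Rows with fewer than 2 finite values, or all-zero rows
#' (undefined similarity), are dropped with a warning.
#'
#' @param m numeric matrix (may contain `NA`).
#' @param axis `"rows"` (default) or `"cols"`.
#' @return list with `merge` (hclust-style merge matrix), `height`
#'   (distance at each merge), `order` (leaf order), `labels`, `dropped`,
#'   and `newick` (the dendrogram as a Newick string).
#' @export
hcluster_cluster3 <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") m <- t(m)
  labels <- rownames(m) %||% paste0("R", seq_len(nrow(m)))
  usable <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    sum(is.finite(v)) >= 2 && sum(v^2, na.rm = TRUE) > 0
  }, logical(1))
  if (any(!usable))
    warning(sprintf("dropped %d row(s) with undefined similarity", sum(!usable)))
  m <- m[usable, , drop = FALSE]
  labels <- labels[usable]
  n <- nrow(m)
  stop_if_not(n >= 2, "need at least two usable rows")

  # active cluster state: centroid sums/counts, member leaves, merge index
  sums <- m; sums[is.na(sums)] <- 0
  cnts <- 1 * !is.na(m)
  centroid <- function(i) {
    v <- sums[i, ] / cnts[i, ]
    v[cnts[i, ] == 0] <- NA
    v
  }
  active <- seq_len(n)
  node_id <- -seq_len(n) # hclust convention: negative = leaf
  leaves <- as.list(seq_len(n))
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- 1 - uncentered_cor(centroid(i), centroid(j))
  }
  merge_mat <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  order_list <- leaves

  for (step in seq_len(n - 1)) {
    # lowest-index pair among minima
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    na_ct <- length(active)
    for (ii in seq_along(active)[-na_ct]) {
      for (jj in (ii + 1):na_ct) {
        i <- active[ii]; j <- active[jj]
        dij <- d[min(i, j), max(i, j)]
        if (is.na(dij)) dij <- Inf
        if (dij < best_d - 1e-12) { best_d <- dij; best <- c(ii, jj) }
      }
    }
    ii <- best[1]; jj <- best[2]
    i <- active[ii]; j <- active[jj]
    merge_mat[step, ] <- c(node_id[i], node_id[j])
    height[step] <- best_d
    # merged cluster replaces slot i
    sums[i, ] <- sums[i, ] + sums[j, ]
    cnts[i, ] <- cnts[i, ] + cnts[j, ]
    leaves[[i]] <- c(leaves[[i]], leaves[[j]])
    node_id[i] <- step
    active <- active[-jj]
    ci <- centroid(i)
    for (k in active) {
      if (k == i) next
      d[min(i, k), max(i, k)] <- 1 - uncentered_cor(ci, centroid(k))
    }
  }
  ord <- leaves[[active]]
  nwk <- build_newick(merge_mat, height, labels)
  list(merge = merge_mat, height = height, order = ord, labels = labels,
       dropped = sum(!usable), newick = nwk)
}

build_newick <- function(merge_mat, height, labels) {
  n <- nrow(merge_mat) + 1
  node_str <- character(n - 1)
  node_h <- numeric(n - 1)
  str_of <- function(id) if (id < 0) labels[-id] else node_str[id]
  h_of <- function(id) if (id < 0) 0 else node_h[id]
  for (s in seq_len(n - 1)) {
    l <- merge_mat[s, 1]; r <- merge_mat[s, 2]
    node_str[s] <- sprintf("(%s:%.6g,%s:%.6g)",
                           str_of(l), max(height[s] - h_of(l), 0),
                           str_of(r), max(height[s] - h_of(r), 0))
    node_h[s] <- height[s]
  }
  paste0(node_str[n - 1], ";")
}
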