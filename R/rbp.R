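#' Load the bundled splicing-RBP roster
#'
#' A replaceable annotation file listing splicing-regulating RBPs by gene
#' symbol and family. The bundled copy (`rbp_roster_synthetic.tsv`) is a
#' synthetic stand-in of ~75 well-known splicing regulators, not any
#' study's curated screen roster; supply your own file of the same shape
#' for real analyses. Synthetic runs generate their own roster.
#'
#' @param path roster TSV (columns `rbp`, `family`); default: bundled file.
#' @return data.frame with `rbp` and `family`.
#' @export
load_rbp_roster <- function(path = system.file("extdata",
                                               "rbp_roster_synthetic.tsv",
                                               package = "spliceHet")) {
  df <- read_tsv(path)
  stop_if_not(all(c("rbp", "family") %in% names(df)),
              "roster must have columns rbp, family")
  df
}

#' Correlate RBP expression with the AS score in one dataset
#'
#' Spearman rank correlation of each RBP's expression against the AS score
#' over shared samples, with Benjamini-Hochberg adjustment within the
#' dataset. Constant expression vectors yield undefined correlations and
#' are recorded as missing.
#'
#' @param expr RBP x sample expression matrix.
#' @param scores data.frame from [as_score()].
#' @param dataset dataset id recorded in the result.
#' @return data.frame with `rbp`, `dataset`, `rho`, `p`, `q`.
#' @export
correlate_rbp_score <- function(expr, scores, dataset = "dataset1") {
  smp <- intersect(colnames(expr),
                   scores$sample_id[!is.na(scores$as_score)])
  stop_if_not(length(smp) >= 10, "need at least 10 shared samples")
  sc <- scores$as_score[match(smp, scores$sample_id)]
  res <- t(vapply(rownames(expr), function(r) {
    v <- expr[r, smp]
    if (length(unique(v)) == 1) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(v, sc, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  out <- data.frame(rbp = rownames(expr), dataset = dataset,
                    rho = res[, 1], p = res[, 2])
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Select RBPs consistently correlated across datasets
#'
#' An RBP is kept iff it is significant (BH `q < alpha`) with the same
#' correlation sign in every dataset.
#'
#' @param results list of data.frames from [correlate_rbp_score()], one per
#'   dataset (>= 2).
#' @param alpha significance level (default 0.05).
#' @return data.frame with `rbp` and `sign` (+1/-1) for consistent RBPs.
#' @export
consistent_rbps <- function(results, alpha = 0.05) {
  stop_if_not(length(results) >= 2, "need results from at least 2 datasets")
  all_res <- do.call(rbind, results)
  if (nrow(all_res) == 0) return(data.frame(rbp = character(), sign = integer()))
  n_ds <- length(results)
  by_rbp <- split(all_res, all_res$rbp)
  keep <- vapply(by_rbp, function(df) {
    nrow(df) == n_ds && !anyNA(df$rho) && all(df$q < alpha) &&
      length(unique(sign(df$rho))) == 1 && all(df$rho != 0)
  }, logical(1))
  out <- data.frame(rbp = names(by_rbp)[keep],
                    sign = vapply(by_rbp[keep], function(df)
                      as.integer(sign(df$rho[1])), integer(1)))
  rownames(out) <- NULL
  out[order(out$rbp), , drop = FALSE]
}

#' RBP-event correlation at single-cell resolution
#'
#' For events detected in more than `min_cells` cells, computes the
#' Spearman correlation between each RBP's expression and the event's PSI
#' over the cells where the event is detected, then clusters the resulting
#' correlation matrix rows with [hcluster_cluster3()].
#'
#' @param sc_expr RBP x cell expression matrix.
#' @param sc_psi a `PsiMatrix` of per-cell PSI (events x cells).
#' @param min_cells detection threshold per event (reference 200).
#' @return list with `rho` (RBP x event matrix; empty if no event passes),
#'   `n_cells` per kept event, and `clustering` (or `NULL` for < 2 RBPs).
#' @export
rbp_event_correlation <- function(sc_expr, sc_psi, min_cells = 200) {
  cells <- intersect(colnames(sc_expr), sc_psi$samples)
  det <- sc_psi$detected[, cells, drop = FALSE]
  n_det <- rowSums(det)
  keep <- sc_psi$events[n_det > min_cells]
  if (length(keep) == 0) {
    return(list(rho = matrix(numeric(), nrow = nrow(sc_expr), ncol = 0,
                             dimnames = list(rownames(sc_expr), NULL)),
                n_cells = integer(), clustering = NULL))
  }
  rho <- matrix(NA_real_, nrow(sc_expr), length(keep),
                dimnames = list(rownames(sc_expr), keep))
  for (e in keep) {
    ok_cells <- cells[det[e, ]]
    psi_v <- sc_psi$psi[e, ok_cells]
    for (r in rownames(sc_expr)) {
      rho[r, e] <- suppressWarnings(
        cor(sc_expr[r, ok_cells], psi_v, method = "spearman"))
    }
  }
  clustering <- if (nrow(rho) >= 2) hcluster_cluster3(rho) else NULL
  list(rho = rho, n_cells = setNames(rowSums(det)[keep], keep),
       clustering = clustering)
}
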