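#' Percent-spliced-in (PSI) estimation with credible intervals
#'
#' Estimates PSI for a two-isoform skipped-exon-style event from inclusion
#' (`I`) and skipping (`S`) junction read counts with effective lengths
#' `lI`, `lS` (number of distinct read positions supporting each isoform).
#'
#' The point estimate is the length-normalized plug-in value
#' \deqn{\hat\psi = I l_S / (I l_S + S l_I),}
#' the form used by rMATS-style counters. For the interval, reads are modeled
#' as \eqn{I \sim Binomial(I+S, \theta)} with
#' \eqn{\theta = \psi l_I / (\psi l_I + (1-\psi) l_S)} (the read-space
#' inclusion probability). A uniform prior on \eqn{\theta} gives the
#' closed-form posterior \eqn{\theta \sim Beta(I+1, S+1)}; PSI quantiles and
#' the posterior mean follow through the strictly increasing transform
#' \eqn{\psi = \theta l_S / (\theta l_S + (1-\theta) l_I)}. The 95% interval
#' is equal-tailed (2.5%/97.5% quantiles), except at count boundaries:
#' when `I == 0` the interval is the one-sided \[0, q95\] and when `S == 0`
#' it is \[q05, 1\] (documented convention; the posterior itself is unchanged).
#'
#' Entries with fewer than `min_reads` informative reads (`I + S`) are marked
#' undetected and all numeric fields are `NA`.
#'
#' @param I,S non-negative integer vectors of inclusion / skipping counts.
#' @param lI,lS positive effective lengths (recycled).
#' @param min_reads detection threshold on `I + S` (default 10).
#' @param conf credible level (default 0.95).
#' @param posterior_mean compute the posterior mean by adaptive quadrature
#'   (exact but slower); if `FALSE` the column is `NA`.
#' @return A data.frame with columns `psi_point`, `psi_posterior_mean`,
#'   `ci_low`, `ci_high`, `ci_width`, `detected`, `n_informative`.
#' @examples
#' estimate_psi(8, 2, lI = 2, lS = 1)
#' @export
estimate_psi <- function(I, S, lI = 1, lS = 1, min_reads = 10, conf = 0.95,
                         posterior_mean = TRUE) {
  n <- max(length(I), length(S), length(lI), length(lS))
  I <- rep_len(I, n); S <- rep_len(S, n)
  lI <- rep_len(lI, n); lS <- rep_len(lS, n)
  stop_if_not(all(I >= 0) && all(S >= 0), "counts must be non-negative")
  stop_if_not(all(lI > 0) && all(lS > 0), "effective lengths must be positive")
  n_inf <- I + S
  detected <- n_inf >= min_reads

  psi_point <- psi_post <- ci_low <- ci_high <- rep(NA_real_, n)
  alpha <- (1 - conf) / 2
  # psi = g(theta); strictly increasing, so quantiles transform directly
  g <- function(theta, lI, lS) theta * lS / (theta * lS + (1 - theta) * lI)
  idx <- which(detected)
  if (length(idx)) {
    a <- I[idx] + 1; b <- S[idx] + 1
    psi_point[idx] <- ifelse(n_inf[idx] == 0, NA_real_,
                             I[idx] * lS[idx] / (I[idx] * lS[idx] + S[idx] * lI[idx]))
    lo_p <- ifelse(I[idx] == 0, 0, ifelse(S[idx] == 0, 2 * alpha, alpha))
    hi_p <- ifelse(S[idx] == 0, 1, ifelse(I[idx] == 0, conf, 1 - alpha))
    ci_low[idx] <- g(qbeta(lo_p, a, b), lI[idx], lS[idx])
    ci_high[idx] <- g(qbeta(hi_p, a, b), lI[idx], lS[idx])
    if (posterior_mean) {
      psi_post[idx] <- vapply(seq_along(idx), function(k) {
        j <- idx[k]
        stats::integrate(function(th) g(th, lI[j], lS[j]) * dbeta(th, a[k], b[k]),
                         0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
      }, numeric(1))
    }
  }
  data.frame(psi_point = psi_point,
             psi_posterior_mean = psi_post,
             ci_low = ci_low, ci_high = ci_high,
             ci_width = ci_high - ci_low,
             detected = detected,
             n_informative = n_inf)
}

#' Build a PSI matrix from a junction-count table
#'
#' Computes one PSI estimate per (event, sample) pair. Pairs absent from the
#' count table, and pairs below the detection threshold, are undetected.
#'
#' @param counts data.frame with columns `event_id`, `sample_id`,
#'   `inc_count`, `skip_count` (long form, one row per pair).
#' @param events event annotation data.frame with columns `event_id`,
#'   `inc_eff_len`, `skip_eff_len`; every counted event must be annotated.
#' @param min_reads detection threshold (see [estimate_psi()]).
#' @param samples optional character vector fixing the sample (column) set
#'   and order; defaults to the samples present in `counts`.
#' @return A `PsiMatrix`: list with matrices `psi`, `ci_width` (events x
#'   samples, `NA` where undetected), logical `detected`, and the id vectors
#'   `events`, `samples`.
#' @export
build_psi_matrix <- function(counts, events, min_reads = 10, samples = NULL) {
  req <- c("event_id", "sample_id", "inc_count", "skip_count")
  stop_if_not(all(req %in% names(counts)), "counts must have columns %s",
              paste(req, collapse = ", "))
  unknown <- setdiff(unique(counts$event_id), events$event_id)
  stop_if_not(length(unknown) == 0, "unknown event id(s): %s",
              paste(head(unknown, 5), collapse = ", "))
  ev_ids <- as.character(events$event_id)
  smp_ids <- samples %||% sort(unique(as.character(counts$sample_id)))

  lI <- setNames(events$inc_eff_len, ev_ids)[as.character(counts$event_id)]
  lS <- setNames(events$skip_eff_len, ev_ids)[as.character(counts$event_id)]
  est <- estimate_psi(counts$inc_count, counts$skip_count, lI, lS,
                      min_reads = min_reads, posterior_mean = FALSE)

  shape <- function(values, default) {
    m <- matrix(default, nrow = length(ev_ids), ncol = length(smp_ids),
                dimnames = list(ev_ids, smp_ids))
    m[cbind(as.character(counts$event_id), as.character(counts$sample_id))] <- values
    m
  }
  psi <- shape(est$psi_point, NA_real_)
  ciw <- shape(est$ci_width, NA_real_)
  det <- shape(est$detected, FALSE)
  structure(list(psi = psi, ci_width = ciw, detected = det,
                 events = ev_ids, samples = smp_ids),
            class = "PsiMatrix")
}

#' @export
print.PsiMatrix <- function(x, ...) {
  cat(sprintf("PsiMatrix: %d events x %d samples; %.1f%% detected\n",
              length(x$events), length(x$samples),
              100 * mean(x$detected)))
  invisible(x)
}

#' Subset a PsiMatrix by events and/or samples
#' @param x a `PsiMatrix`.
#' @param events,samples character vectors of ids to keep (default: all).
#' @return A `PsiMatrix`.
#' @export
subset_psi <- function(x, events = NULL, samples = NULL) {
  ev <- events %||% x$events
  smp <- samples %||% x$samples
  stop_if_not(all(ev %in% x$events), "unknown event id(s) in subset")
  stop_if_not(all(smp %in% x$samples), "unknown sample id(s) in subset")
  structure(list(psi = x$psi[ev, smp, drop = FALSE],
                 ci_width = x$ci_width[ev, smp, drop = FALSE],
                 detected = x$detected[ev, smp, drop = FALSE],
                 events = ev, samples = smp),
            class = "PsiMatrix")
}

#' Impute undetected PSI entries by per-event median
#'
#' Replaces `NA` entries with the median of the event's detected values
#' (0.5 for events with no detected value). Used before clustering and
#' forest fitting, which require complete matrices.
#'
#' @param x a `PsiMatrix` or a numeric matrix with `NA`s.
#' @return A plain numeric matrix (events x samples) without `NA`s.
#' @export
impute_psi <- function(x) {
  m <- if (inherits(x, "PsiMatrix")) x$psi else x
  med <- apply(m, 1, function(r) {
    v <- median(r, na.rm = TRUE)
    if (is.na(v)) 0.5 else v
  })
  na <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na)) m[na] <- med[na[, 1]]
  m
}
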