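#' Filtering configuration
#'
#' Thresholds for sample QC and the three-criterion selection of
#' informative, reliable events: (a) PSI range `Max(PSI) - Min(PSI) >
#' range_min`; (b) `SD(PSI) > sd_min`; (c) 95% CI width `< ci_width_max` in
#' more than `ci_frac_min` of samples. Samples are dropped beforehand when
#' their undetected-event fraction exceeds `sample_undetected_max`.
#' Inequalities are strict on the sides shown. All statistics are computed
#' over detected entries only (SD with the n-1 denominator); events must
#' additionally be detected in at least `detect_frac_min` of QC-passed
#' samples to avoid two-sample variance artifacts.
#'
#' @param range_min minimum PSI range (default 0.6).
#' @param sd_min minimum PSI standard deviation (default 0.1).
#' @param ci_width_max CI-width cutoff (default 0.5).
#' @param ci_frac_min required fraction of narrow-CI samples (default 0.8).
#' @param sample_undetected_max sample QC cutoff on the undetected fraction
#'   (default 0.4).
#' @param detect_frac_min minimum detection fraction per event (default 0.5).
#' @return A `FilterConfig` list.
#' @export
filter_config <- function(range_min = 0.6, sd_min = 0.1, ci_width_max = 0.5,
                          ci_frac_min = 0.8, sample_undetected_max = 0.4,
                          detect_frac_min = 0.5) {
  cfg <- as.list(environment())
  for (nm in names(cfg)) {
    stop_if_not(cfg[[nm]] >= 0 && cfg[[nm]] <= 1, "%s must lie in [0,1]", nm)
  }
  structure(cfg, class = "FilterConfig")
}

#' Sample quality control by undetected-event fraction
#'
#' Drops a sample iff its fraction of undetected events (over all annotated
#' events in the matrix) strictly exceeds `sample_undetected_max`.
#'
#' @param x a `PsiMatrix`.
#' @param cfg a [filter_config()].
#' @return list with `kept` and `dropped` sample id vectors and the
#'   per-sample `undetected_frac`.
#' @export
qc_samples <- function(x, cfg = filter_config()) {
  stop_if_not(length(x$samples) > 0 && length(x$events) > 0,
              "matrix must be non-empty")
  frac <- 1 - colMeans(x$detected)
  drop <- frac > cfg$sample_undetected_max
  list(kept = x$samples[!drop], dropped = x$samples[drop],
       undetected_frac = setNames(frac, x$samples))
}

#' Three-criterion event filter
#'
#' Keeps an event iff, over its detected entries: range > `range_min`, SD >
#' `sd_min`, and the fraction of entries with CI width < `ci_width_max`
#' exceeds `ci_frac_min`; the event must also be detected in at least
#' `detect_frac_min` of the samples. Events with fewer than 2 detected
#' entries fail the range and SD criteria by definition.
#'
#' @param x a `PsiMatrix` (after [qc_samples()]).
#' @param cfg a [filter_config()].
#' @return list with `kept` event ids and `report`, a per-event data.frame
#'   of criterion booleans and the underlying statistics.
#' @export
filter_events <- function(x, cfg = filter_config()) {
  n_smp <- length(x$samples)
  stats_ <- t(vapply(seq_along(x$events), function(i) {
    v <- x$psi[i, ][x$detected[i, ]]
    w <- x$ci_width[i, ][x$detected[i, ]]
    n_det <- length(v)
    c(n_det = n_det,
      range = if (n_det >= 2) max(v) - min(v) else NA_real_,
      sd = if (n_det >= 2) sd(v) else NA_real_,
      narrow_frac = if (n_det >= 1) mean(w < cfg$ci_width_max) else NA_real_)
  }, numeric(4)))
  report <- data.frame(event_id = x$events, stats_)
  report$pass_range <- !is.na(report$range) & report$range > cfg$range_min
  report$pass_sd <- !is.na(report$sd) & report$sd > cfg$sd_min
  report$pass_ci <- !is.na(report$narrow_frac) &
    report$narrow_frac > cfg$ci_frac_min
  report$pass_detect <- report$n_det >= cfg$detect_frac_min * n_smp
  report$kept <- report$pass_range & report$pass_sd & report$pass_ci &
    report$pass_detect
  list(kept = report$event_id[report$kept], report = report)
}

#' Intersect kept-event sets across datasets
#'
#' @param kept_sets list of event-id vectors, one per dataset.
#' @return Character vector of events kept in every dataset (warns when
#'   empty).
#' @export
intersect_across_datasets <- function(kept_sets) {
  stop_if_not(length(kept_sets) >= 1, "need at least one dataset")
  out <- Reduce(intersect, kept_sets)
  if (length(out) == 0) warning("empty consensus event set")
  out
}
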