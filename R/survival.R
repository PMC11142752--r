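#' Kaplan-Meier comparison of AS-score groups with log-rank test
#'
#' Splits samples at a score quantile (default the median), estimates
#' Kaplan-Meier curves per group and compares them with the log-rank test.
#'
#' @param scores data.frame from [as_score()] (`sample_id`, `as_score`).
#' @param survival data.frame with `sample_id`, `time` (> 0), `status`
#'   (0 censored / 1 event).
#' @param cut quantile for the split (default 0.5 = median split).
#' @return list with `fit` (a `survfit` object), `chisq`, `p`, `groups`
#'   (named factor "low"/"high").
#' @export
km_logrank <- function(scores, survival, cut = 0.5) {
  df <- merge(scores, survival, by = "sample_id")
  df <- df[!is.na(df$as_score), ]
  stop_if_not(all(df$time > 0), "survival times must be positive")
  stop_if_not(all(df$status %in% c(0, 1)), "status must be 0/1")
  thr <- quantile(df$as_score, cut)
  grp <- factor(ifelse(df$as_score > thr, "high", "low"),
                levels = c("low", "high"))
  tab <- table(grp)
  stop_if_not(length(tab) == 2 && all(tab >= 2),
              "degenerate grouping: need >= 2 samples in each of 2 groups")
  srv <- survival::Surv(df$time, df$status)
  fit <- survival::survfit(srv ~ grp)
  sd_ <- survival::survdiff(srv ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd_$chisq), p = p,
       groups = setNames(grp, df$sample_id))
}

#' Multivariable Cox proportional-hazards fit for the AS score
#'
#' Fits `Surv(time, status) ~ as_score + covariates` with Efron tie
#' handling and returns hazard ratios with 95% confidence intervals.
#' Constant or duplicated covariate columns raise an error;
#' non-convergence warnings from the fitter are propagated.
#'
#' @param scores data.frame from [as_score()].
#' @param survival data.frame with `sample_id`, `time`, `status` and any
#'   covariate columns.
#' @param covariates character vector of covariate column names in
#'   `survival` (categorical columns are treated as factors).
#' @return data.frame with one row per model term: `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`; the fitted model is attached as attribute `fit`.
#' @export
cox_multivariable <- function(scores, survival, covariates = character()) {
  df <- merge(scores, survival, by = "sample_id")
  df <- df[!is.na(df$as_score), ]
  missing_cov <- setdiff(covariates, names(df))
  stop_if_not(length(missing_cov) == 0, "covariate(s) not found: %s",
              paste(missing_cov, collapse = ", "))
  for (cv in covariates) {
    stop_if_not(length(unique(df[[cv]])) > 1, "constant covariate: %s", cv)
    if (is.character(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  }
  if (length(covariates) > 1) {
    for (i in seq_len(length(covariates) - 1)) {
      for (j in (i + 1):length(covariates)) {
        stop_if_not(!identical(df[[covariates[i]]], df[[covariates[j]]]),
                    "duplicated covariate columns: %s, %s",
                    covariates[i], covariates[j])
      }
    }
  }
  form <- stats::as.formula(paste(
    "survival::Surv(time, status) ~ as_score",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- survival::coxph(form, data = df, ties = "efron")
  sm <- summary(fit)
  out <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$conf.int[, "exp(coef)"],
                    ci_low = sm$conf.int[, "lower .95"],
                    ci_high = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"])
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
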