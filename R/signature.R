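#' Rank splicing events by random-forest Mean Decrease Gini
#'
#' Fits a bootstrap CART forest classifying cluster labels from event PSI
#' profiles and ranks events by Mean Decrease Gini (MDG): the total
#' node-size-weighted Gini impurity decrease attributed to each event,
#' averaged over trees. The top `n_select` events form the signature
#' candidate set.
#'
#' @param x a `PsiMatrix` or events x samples matrix, typically restricted
#'   to representative samples; missing values are median-imputed.
#' @param labels named cluster labels covering the samples of `x`.
#' @param n_select events to select (reference 200).
#' @param n_trees forest size (default 2000; Gini-importance rankings over
#'   ~1000+ candidate events need substantially more trees than the
#'   classical 500 to stabilize — see the methods vignette).
#' @param mtry features per split (default `floor(sqrt(p))`).
#' @param min_node minimum samples per leaf (default 10). A permissive
#'   nodesize lets trees memorize stray samples in tiny leaves, leaking
#'   importance onto uninformative events; a moderate leaf floor keeps the
#'   ranking on reproducible structure.
#' @param seed integer seed.
#' @return A `SignatureModel` fragment: list with `importance` (named MDG
#'   vector, descending), `selected_events`.
#' @export
rank_events_by_mdg <- function(x, labels, n_select = 200, n_trees = 2000,
                               mtry = NULL, min_node = 10, seed = 1) {
  m <- impute_psi(x)
  samples <- colnames(m)
  stop_if_not(all(samples %in% names(labels)), "labels must cover all samples")
  y <- factor(labels[samples])
  stop_if_not(nlevels(y) >= 2, "need at least two classes")
  p <- nrow(m)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  set.seed(seed)
  imp <- .rf_gini_importance(t(m), as.integer(y) - 1L, nlevels(y),
                             as.integer(n_trees), as.integer(mtry),
                             as.integer(min_node))
  names(imp) <- rownames(m)
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  structure(list(importance = imp,
                 selected_events = names(imp)[seq_len(min(n_select, p))]),
            class = "SignatureModel")
}

#' Assign selected events to survival-direction groups
#'
#' Determines the worse-survival cluster (lower median Kaplan-Meier
#' survival, log-rank recorded) and assigns each selected event to group 1
#' if its mean detected PSI is higher in the worse cluster than in the
#' other cluster, else group 2. Within each group the top `n_per_group`
#' events by MDG are retained (all, with a warning, if fewer exist).
#' With `direction_by = "survival"` the cluster step is replaced by the sign
#' of the Spearman correlation between event PSI and a per-sample risk
#' ranking (longer observed survival = lower risk), an alternative reading
#' of the direction rule.
#'
#' @param x a `PsiMatrix` covering the clustered samples.
#' @param model a `SignatureModel` from [rank_events_by_mdg()].
#' @param labels named cluster labels.
#' @param survival data.frame with `sample_id`, `time`, `status`.
#' @param n_per_group events kept per group (reference 20).
#' @param direction_by `"cluster"` (default) or `"survival"`.
#' @param worse_cluster optional explicit override; required if the cluster
#'   median survivals are exactly equal.
#' @return The model extended with `group1`, `group2`, `worse_cluster`,
#'   `logrank_p`.
#' @export
assign_groups <- function(x, model, labels, survival,
                          n_per_group = 20,
                          direction_by = c("cluster", "survival"),
                          worse_cluster = NULL) {
  direction_by <- match.arg(direction_by)
  events <- model$selected_events
  stop_if_not(all(events %in% x$events), "model events missing from matrix")
  smp <- intersect(x$samples, survival$sample_id)
  stop_if_not(length(smp) > 0, "survival table covers no matrix samples")
  surv <- survival[match(smp, survival$sample_id), ]
  lab <- labels[smp]

  logrank_p <- NA_real_
  if (direction_by == "cluster") {
    sd_ <- survival::survdiff(survival::Surv(surv$time, surv$status) ~ lab)
    logrank_p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1,
                               lower.tail = FALSE)
    if (is.null(worse_cluster)) {
      fit <- survival::survfit(survival::Surv(surv$time, surv$status) ~ lab)
      med <- summary(fit)$table[, "median"]
      med[is.na(med)] <- Inf # never reaching 50% mortality = better survival
      stop_if_not(length(unique(med)) > 1,
                  "equal median survival between clusters; pass worse_cluster explicitly")
      worse_cluster <- sort(unique(lab))[which.min(med)]
    }
    in_worse <- lab == worse_cluster
    dir_up <- vapply(events, function(e) {
      v <- x$psi[e, smp]; d <- x$detected[e, smp]
      mean(v[d & in_worse], na.rm = TRUE) > mean(v[d & !in_worse], na.rm = TRUE)
    }, logical(1))
  } else {
    # risk ranking: deaths ranked by time (earlier = worse), censored after
    risk <- rank(ifelse(surv$status == 1, surv$time, max(surv$time) + surv$time))
    dir_up <- vapply(events, function(e) {
      v <- x$psi[e, smp]
      ok <- x$detected[e, smp]
      suppressWarnings(cor(v[ok], risk[ok], method = "spearman")) < 0
    }, logical(1))
    worse_cluster <- NA
  }

  pick <- function(ids) {
    if (length(ids) < n_per_group)
      warning(sprintf("only %d candidate events for a group of %d",
                      length(ids), n_per_group))
    ids[order(-model$importance[ids], ids)][seq_len(min(n_per_group, length(ids)))]
  }
  model$group1 <- pick(events[dir_up])
  model$group2 <- pick(events[!dir_up])
  model$worse_cluster <- worse_cluster
  model$logrank_p <- logrank_p
  model
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %d ranked events", length(x$importance)))
  if (!is.null(x$group1))
    cat(sprintf("; groups %d/%d (worse cluster: %s)",
                length(x$group1), length(x$group2), x$worse_cluster))
  cat("\n")
  invisible(x)
}

#' Compute the AS score
#'
#' Per-sample score = mean detected PSI over group-1 events minus mean
#' detected PSI over group-2 events. The score is `NA` when either group has
#' fewer than `min_detected` detected events in that sample. Scoring uses
#' the frozen groups; no refitting occurs, so the score is transferable to
#' new datasets (absent events simply reduce the group mean's support).
#'
#' @param x a `PsiMatrix`.
#' @param model a `SignatureModel` with groups assigned.
#' @param min_detected minimum detected events per group (default 10).
#' @return data.frame with `sample_id`, `as_score`, `n_group1_detected`,
#'   `n_group2_detected`.
#' @export
as_score <- function(x, model, min_detected = 10) {
  stop_if_not(length(model$group1) > 0 && length(model$group2) > 0,
              "model groups must be non-empty")
  g1 <- intersect(model$group1, x$events)
  g2 <- intersect(model$group2, x$events)
  group_mean <- function(ids) {
    psi <- x$psi[ids, , drop = FALSE]
    det <- x$detected[ids, , drop = FALSE]
    psi[!det] <- NA
    list(mean = colMeans(psi, na.rm = TRUE), n = colSums(det))
  }
  m1 <- group_mean(g1); m2 <- group_mean(g2)
  score <- m1$mean - m2$mean
  score[m1$n < min_detected | m2$n < min_detected] <- NA_real_
  data.frame(sample_id = x$samples, as_score = unname(score),
             n_group1_detected = unname(m1$n),
             n_group2_detected = unname(m2$n))
}

#' Serialize / restore a signature model as TSV
#' @param model a `SignatureModel` with groups assigned.
#' @param path TSV path with columns `event_id`, `mdg`, `group`.
#' @export
write_signature_model <- function(model, path) {
  grp <- rep("selected", length(model$selected_events))
  names(grp) <- model$selected_events
  grp[model$group1] <- "group1"
  grp[model$group2] <- "group2"
  df <- data.frame(event_id = model$selected_events,
                   mdg = unname(model$importance[model$selected_events]),
                   group = unname(grp))
  write_tsv(df, path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  df <- read_tsv(path)
  imp <- setNames(df$mdg, df$event_id)
  structure(list(importance = imp, selected_events = df$event_id,
                 group1 = df$event_id[df$group == "group1"],
                 group2 = df$event_id[df$group == "group2"],
                 worse_cluster = NA, logrank_p = NA_real_),
            class = "SignatureModel")
}
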