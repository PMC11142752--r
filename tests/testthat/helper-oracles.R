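# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles (grid quadrature, exhaustive loops,
# regexes) and never call the implementation paths they check.

# Grid-quadrature oracle for the PSI posterior: theta ~ Beta(I+1, S+1),
# psi = theta*lS / (theta*lS + (1-theta)*lI). Posterior mean and equal-tailed
# quantiles from a midpoint grid; mirrors the documented boundary convention
# (I == 0 -> one-sided [0, q95]; S == 0 -> [q05, 1]).
psi_posterior_oracle <- function(I, S, lI, lS, n_grid = 10001) {
  theta <- seq(0, 1, length.out = n_grid)
  mid <- (theta[-1] + theta[-n_grid]) / 2
  dens <- dbeta(mid, I + 1, S + 1)
  w <- diff(theta) * dens
  w <- w / sum(w)
  psi <- mid * lS / (mid * lS + (1 - mid) * lI)
  cdf <- cumsum(w)
  qpsi <- function(p) psi[which(cdf >= p)[1]]
  lo_p <- if (I == 0) 0 else if (S == 0) 0.05 else 0.025
  hi_p <- if (S == 0) 1 else if (I == 0) 0.95 else 0.975
  list(mean = sum(w * psi),
       ci_low = if (lo_p == 0) 0 else qpsi(lo_p),
       ci_high = if (hi_p == 1) 1 else qpsi(hi_p))
}

# Exhaustive three-criterion filter + sample QC oracle (plain loops).
filter_oracle <- function(psi, ciw, det, cfg) {
  n_ev <- nrow(psi); n_smp <- ncol(psi)
  drop_smp <- logical(n_smp)
  for (j in seq_len(n_smp)) {
    undet <- sum(!det[, j]) / n_ev
    drop_smp[j] <- undet > cfg$sample_undetected_max
  }
  keep_smp <- which(!drop_smp)
  kept_ev <- logical(n_ev)
  for (i in seq_len(n_ev)) {
    v <- c(); w <- c()
    for (j in keep_smp) if (det[i, j]) { v <- c(v, psi[i, j]); w <- c(w, ciw[i, j]) }
    if (length(v) < 2) next
    ok_a <- (max(v) - min(v)) > cfg$range_min
    ok_b <- sd(v) > cfg$sd_min
    ok_c <- mean(w < cfg$ci_width_max) > cfg$ci_frac_min
    ok_d <- length(v) >= cfg$detect_frac_min * length(keep_smp)
    kept_ev[i] <- ok_a && ok_b && ok_c && ok_d
  }
  list(kept_samples = keep_smp, kept_events = which(kept_ev))
}

# Naive O(n^3) centroid-linkage oracle with uncentered-correlation distance,
# pairwise-complete entries, lowest-index tie-breaking.
centroid_linkage_oracle <- function(m) {
  n <- nrow(m)
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  ucor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok) || sum(x[ok]^2) == 0 || sum(y[ok]^2) == 0) return(NA_real_)
    sum(x[ok] * y[ok]) / sqrt(sum(x[ok]^2) * sum(y[ok]^2))
  }
  cent <- function(members) {
    v <- colMeans(m[members, , drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA
    v
  }
  for (s in seq_len(n - 1)) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        d <- 1 - ucor(cent(clusters[[i]]), cent(clusters[[j]]))
        if (is.na(d)) d <- Inf
        if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merges[s, ] <- c(ids[i], ids[j])
    heights[s] <- best_d
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- s
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merges, height = heights)
}

# Regex oracle for IUPAC matching (U == T on both sides).
iupac_regex_oracle <- function(pattern, sequences) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  pat <- paste0(vapply(strsplit(toupper(pattern), "")[[1]], function(l)
    paste0("[", sets[[l]], "]"), character(1)), collapse = "")
  grepl(pat, chartr("U", "T", toupper(sequences)))
}

# Per-position table-lookup oracle for WMM scores.
wmm_score_oracle <- function(seq_, pwm, background) {
  ch <- strsplit(seq_, "")[[1]]
  sum(vapply(seq_along(ch), function(j)
    log2(pwm[ch[j], j] / background[ch[j]]), numeric(1)))
}

# Construct a PsiMatrix directly from matrices (bypasses build_psi_matrix).
make_psimatrix <- function(psi, ciw = NULL, det = NULL) {
  ev <- rownames(psi) %||% sprintf("EV%03d", seq_len(nrow(psi)))
  smp <- colnames(psi) %||% sprintf("S%03d", seq_len(ncol(psi)))
  if (is.null(det)) det <- !is.na(psi)
  if (is.null(ciw)) ciw <- matrix(0.1, nrow(psi), ncol(psi))
  dimnames(psi) <- dimnames(ciw) <- dimnames(det) <- list(ev, smp)
  psi[!det] <- NA; ciw[!det] <- NA
  structure(list(psi = psi, ci_width = ciw, detected = det,
                 events = ev, samples = smp), class = "PsiMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
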