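#' Simulation configuration
#'
#' Parameters of the ground-truth generator that emulates the statistical
#' structure of multi-cohort glioma splicing data: a latent per-sample
#' splicing score drawn from a two-mode continuum, informative events whose
#' PSI rises (group 1) or falls (group 2) with the score, junction counts
#' with effective-length bias, survival driven by the true AS score, RBP
#' expression coupled to the score, sparse state-structured single-cell
#' coverage, and flank sequences with planted degenerate motifs.
#'
#' Defaults mirror the scale of the source cohorts where stated (1,300
#' filtered events, 200 signature events, 276 RBPs with 29 coupled, per-unit
#' hazard ratio 3) and otherwise use values a bulk RNA-seq analyst would call
#' realistic (see the methods vignette).
#'
#' @param n_samples number of bulk samples.
#' @param n_events total number of splicing events.
#' @param n_informative events coupled to the latent score (`<= n_events`).
#' @param frac_group1 fraction of informative events with positive coupling.
#' @param latent_mixture list with mixture modes `m1`, `m2` in (0,1) and
#'   shared `spread` (Beta concentration; larger = tighter modes).
#' @param coupling_strength logit-scale slope magnitude `b` for informative
#'   events.
#' @param psi_concentration Beta concentration kappa of biological PSI noise.
#' @param reads_per_event mean total informative reads per (event, sample).
#' @param reads_dispersion negative-binomial size of the read-depth draw.
#' @param survival_beta log-hazard per unit of the true AS score.
#' @param censor_rate target fraction of censored samples.
#' @param n_rbp_total,n_rbp_coupled RBP roster size and number coupled.
#' @param rbp_rho target Spearman correlation of coupled RBPs (|rho| < 1).
#' @param sc_n_patients,sc_states,sc_cells_per_state,sc_reads_per_cell_event
#'   single-cell shape: patients, cellular-state labels, cells per
#'   (patient, state), and Poisson mean reads per cell per event.
#' @param motif_plant_rate per-sequence motif planting probability.
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_samples = 300,
                       n_events = 1300,
                       n_informative = 200,
                       frac_group1 = 0.5,
                       latent_mixture = list(m1 = 0.25, m2 = 0.75, spread = 40),
                       coupling_strength = 6,
                       psi_concentration = 100,
                       reads_per_event = 100,
                       reads_dispersion = 10,
                       survival_beta = log(3),
                       censor_rate = 0.3,
                       n_rbp_total = 276,
                       n_rbp_coupled = 29,
                       rbp_rho = 0.8,
                       sc_n_patients = 4,
                       sc_states = c("NPC.1", "NPC.2", "OPC-like", "AC-like",
                                     "MES.1", "stem-like"),
                       sc_cells_per_state = 100,
                       sc_reads_per_cell_event = 2,
                       motif_plant_rate = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stop_if_not(n_informative <= n_events, "n_informative must be <= n_events")
    stop_if_not(frac_group1 >= 0 && frac_group1 <= 1, "frac_group1 in [0,1]")
    stop_if_not(censor_rate >= 0 && censor_rate <= 1, "censor_rate in [0,1]")
    stop_if_not(motif_plant_rate >= 0 && motif_plant_rate <= 1,
                "motif_plant_rate in [0,1]")
    stop_if_not(psi_concentration > 0, "psi_concentration must be > 0")
    stop_if_not(latent_mixture$m1 != latent_mixture$m2, "mixture modes must differ")
    stop_if_not(latent_mixture$m1 > 0 && latent_mixture$m1 < 1 &&
                latent_mixture$m2 > 0 && latent_mixture$m2 < 1,
                "mixture modes must lie in (0,1)")
    stop_if_not(abs(rbp_rho) < 1, "|rbp_rho| must be < 1")
    stop_if_not(n_rbp_coupled <= n_rbp_total, "n_rbp_coupled <= n_rbp_total")
  })
  structure(cfg, class = "SimConfig")
}

# Beta draw parameterized by mode m and concentration (spread): mode of
# Beta(1 + m*s, 1 + (1-m)*s) is m.
rbeta_mode <- function(n, mode, spread) {
  rbeta(n, 1 + mode * spread, 1 + (1 - mode) * spread)
}

#' Simulate a bulk junction-count dataset with ground truth
#'
#' Generative model, per sample i and event j:
#' \itemize{
#'   \item latent score \eqn{s_i} from an equal-weight two-mode Beta mixture;
#'   \item mean PSI \eqn{\mu_{ij} = logistic(a_j + b_j s_i)} with intercepts
#'     \eqn{a_j \sim U(logit 0.15, logit 0.85)} and slopes \eqn{b_j = +b}
#'     (group 1), \eqn{-b} (group 2) or 0 (noise);
#'   \item realized \eqn{\psi_{ij} \sim Beta(\mu\kappa, (1-\mu)\kappa)};
#'   \item total reads \eqn{n_{ij}} negative-binomial; inclusion reads
#'     binomial with read-space probability
#'     \eqn{\theta = \psi l_I / (\psi l_I + (1-\psi) l_S)};
#'   \item survival exponential with hazard \eqn{\propto exp(\beta AS_i)}
#'     where \eqn{AS_i} is the true AS score (mean group-1 PSI minus mean
#'     group-2 PSI), under uniform administrative censoring calibrated to
#'     the target censor rate.
#' }
#'
#' @param config a [sim_config()].
#' @param dataset_name name recorded in outputs (default "sim").
#' @return list with `counts` (long junction-count table), `events`
#'   (annotation), `metadata` (sample table with survival and covariates),
#'   and `truth` (a `SimTruth`: latent scores, cluster labels, event roles
#'   and parameters, true PSI matrix, true AS score, survival beta).
#' @export
simulate_bulk <- function(config, dataset_name = "sim") {
  stop_if_not(inherits(config, "SimConfig"), "config must be a SimConfig")
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_samples; p <- config$n_events
  m1 <- config$latent_mixture$m1; m2 <- config$latent_mixture$m2
  spread <- config$latent_mixture$spread

  cluster_label <- sample(rep_len(1:2, n))
  s <- ifelse(cluster_label == 1,
              rbeta_mode(n, m1, spread), rbeta_mode(n, m2, spread))
  sample_id <- sprintf("%s_S%03d", dataset_name, seq_len(n))

  n_inf <- config$n_informative
  n_g1 <- round(config$frac_group1 * n_inf)
  role <- c(rep("group1", n_g1), rep("group2", n_inf - n_g1),
            rep("noise", p - n_inf))
  b_j <- c(rep(config$coupling_strength, n_g1),
           rep(-config$coupling_strength, n_inf - n_g1),
           rep(0, p - n_inf))
  a_j <- runif(p, logit(0.15), logit(0.85))
  # center informative events so both PSI modes stay visible on [0,1]
  a_j[role != "noise"] <- a_j[role != "noise"] - b_j[role != "noise"] * 0.5
  event_id <- sprintf("EV%05d", seq_len(p))

  mu <- plogis(outer(a_j, rep(1, n)) + outer(b_j, s))
  kappa <- config$psi_concentration
  true_psi <- matrix(rbeta(p * n, mu * kappa, (1 - mu) * kappa), p, n,
                     dimnames = list(event_id, sample_id))

  lI <- rep(2, p); lS <- rep(1, p)
  theta <- true_psi * lI / (true_psi * lI + (1 - true_psi) * lS)
  tot <- matrix(rnbinom(p * n, mu = config$reads_per_event,
                        size = config$reads_dispersion), p, n)
  inc <- matrix(rbinom(p * n, as.vector(tot), as.vector(theta)), p, n)
  skp <- tot - inc

  counts <- data.frame(event_id = rep(event_id, times = n),
                       sample_id = rep(sample_id, each = p),
                       inc_count = as.integer(inc),
                       skip_count = as.integer(skp))

  as_true <- as_true_score(true_psi, role)
  hazard <- log(2) / 730 * exp(config$survival_beta * as_true)
  t_event <- rexp(n, rate = hazard)
  if (config$censor_rate > 0) {
    cmax <- calibrate_censor_horizon(t_event, config$censor_rate)
    c_time <- runif(n, 0, cmax)
  } else c_time <- rep(Inf, n)
  time <- pmin(t_event, c_time)
  status <- as.integer(t_event <= c_time)

  metadata <- data.frame(sample_id = sample_id,
                         time = time, status = status,
                         age = round(rnorm(n, 55, 12), 1),
                         sex = sample(c("F", "M"), n, replace = TRUE))

  events <- data.frame(event_id = event_id,
                       gene = sprintf("GENE%04d", seq_len(p)),
                       event_type = sample(c("SE", "MXE", "A5SS", "A3SS", "RI"),
                                           p, replace = TRUE,
                                           prob = c(0.6, 0.2, 0.08, 0.08, 0.04)),
                       chrom = sample(paste0("chr", 1:22), p, replace = TRUE),
                       strand = sample(c("+", "-"), p, replace = TRUE),
                       exon_start = as.integer(seq_len(p) * 1000L),
                       exon_end = as.integer(seq_len(p) * 1000L + 120L),
                       inc_eff_len = lI, skip_eff_len = lS,
                       role = role)

  truth <- structure(list(latent_score = setNames(s, sample_id),
                          cluster_label = setNames(cluster_label, sample_id),
                          event_role = setNames(role, event_id),
                          event_params = data.frame(event_id = event_id,
                                                    a = a_j, b = b_j),
                          true_psi = true_psi,
                          as_true = setNames(as_true, sample_id),
                          survival_beta = config$survival_beta),
                     class = "SimTruth")
  list(counts = counts, events = events, metadata = metadata, truth = truth)
}

#' True AS score from a true-PSI matrix and event roles
#' @param true_psi events x samples matrix.
#' @param role per-event roles ("group1"/"group2"/"noise").
#' @return Per-sample true score (mean group-1 PSI minus mean group-2 PSI).
#' @export
as_true_score <- function(true_psi, role) {
  g1 <- role == "group1"; g2 <- role == "group2"
  m1 <- if (any(g1)) colMeans(true_psi[g1, , drop = FALSE]) else 0
  m2 <- if (any(g2)) colMeans(true_psi[g2, , drop = FALSE]) else 0
  m1 - m2
}

# Solve for the uniform censoring horizon giving the target censor fraction:
# with C ~ U(0, cmax), P(censor | T = t) = min(t / cmax, 1).
calibrate_censor_horizon <- function(t_event, censor_rate) {
  f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censor_rate
  hi <- max(t_event) / censor_rate * 2
  uniroot(f, lower = min(t_event) * 1e-6, upper = hi)$root
}

#' Simulate single-cell junction counts structured by cellular state
#'
#' Each patient carries a latent score (drawn from the same two-mode mixture
#' as bulk samples) and each cellular state a state score in \[0,1\]; the
#' effective latent value for a (patient, state) pseudo-population is the
#' mean of the two. True PSI per (event, patient, state) then follows the
#' bulk generative model. Per-cell coverage is sparse: total reads per
#' (cell, event) are Poisson with mean `sc_reads_per_cell_event` and
#' inclusion reads are binomial in read space as in [simulate_bulk()].
#'
#' @param config a [sim_config()] with the `sc_*` fields set.
#' @param bulk_truth a `SimTruth` from [simulate_bulk()] supplying event
#'   parameters and roles.
#' @return list with `counts` (cell_id, event_id, inc_count, skip_count;
#'   zero-coverage rows omitted), `annotation` (cell_id, patient, state),
#'   `events` (the event ids used) and `truth` (state scores, patient
#'   scores, true PSI per pseudo-population).
#' @export
simulate_sc <- function(config, bulk_truth) {
  stop_if_not(inherits(config, "SimConfig"), "config must be a SimConfig")
  stop_if_not(inherits(bulk_truth, "SimTruth"), "bulk_truth must be a SimTruth")
  stop_if_not(length(config$sc_states) > 0, "need at least one cellular state")
  stop_if_not(config$sc_cells_per_state > 0, "need at least one cell per state")
  set.seed(derive_seed(config$seed, 2))

  states <- config$sc_states
  n_pat <- config$sc_n_patients
  patients <- sprintf("P%02d", seq_len(n_pat))
  m1 <- config$latent_mixture$m1; m2 <- config$latent_mixture$m2
  spread <- config$latent_mixture$spread
  pat_cluster <- rep_len(1:2, n_pat)
  s_pat <- ifelse(pat_cluster == 1, rbeta_mode(n_pat, m1, spread),
                  rbeta_mode(n_pat, m2, spread))
  state_score <- setNames(seq(0.9, 0.1, length.out = length(states)), states)

  ev <- bulk_truth$event_params
  p <- nrow(ev)
  kappa <- config$psi_concentration
  lI <- 2; lS <- 1

  ann <- expand.grid(patient = patients, state = states,
                     cell = seq_len(config$sc_cells_per_state),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ann$cell_id <- sprintf("%s_%s_C%03d", ann$patient, ann$state, ann$cell)
  ann <- ann[, c("cell_id", "patient", "state")]

  # true PSI per (event, patient-state)
  pb_key <- paste(rep(patients, each = length(states)),
                  rep(states, times = n_pat), sep = ":")
  lat <- (rep(s_pat, each = length(states)) +
            rep(state_score, times = n_pat)) / 2
  mu <- plogis(outer(ev$a, rep(1, length(lat))) + outer(ev$b, lat))
  true_psi <- matrix(rbeta(length(mu), mu * kappa, (1 - mu) * kappa),
                     nrow = p, dimnames = list(ev$event_id, pb_key))

  lam <- config$sc_reads_per_cell_event
  recs <- vector("list", nrow(ann))
  theta_all <- true_psi * lI / (true_psi * lI + (1 - true_psi) * lS)
  for (ci in seq_len(nrow(ann))) {
    key <- paste(ann$patient[ci], ann$state[ci], sep = ":")
    tot <- rpois(p, lam)
    nz <- which(tot > 0)
    if (!length(nz)) next
    inc <- rbinom(length(nz), tot[nz], theta_all[nz, key])
    recs[[ci]] <- data.frame(cell_id = ann$cell_id[ci],
                             event_id = ev$event_id[nz],
                             inc_count = inc,
                             skip_count = tot[nz] - inc)
  }
  counts <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(counts)) {
    counts <- data.frame(cell_id = character(), event_id = character(),
                         inc_count = integer(), skip_count = integer())
  }
  rownames(counts) <- NULL
  truth <- list(patient_score = setNames(s_pat, patients),
                patient_cluster = setNames(pat_cluster, patients),
                state_score = state_score,
                true_psi = true_psi)
  list(counts = counts, annotation = ann, events = ev$event_id, truth = truth)
}

#' Simulate RBP expression coupled to the latent splicing score
#'
#' Coupled RBPs are generated to hit a target Spearman correlation with the
#' latent score: the score's normal ranks are mixed with Gaussian noise at
#' the Pearson level \eqn{\rho_P = 2 sin(\pi \rho_S / 6)} that yields the
#' requested Spearman \eqn{\rho_S} for bivariate normal pairs, then mapped
#' through a monotone log-normal transform (which leaves Spearman
#' untouched). Half the coupled RBPs (rounded up) are positive, the rest
#' negative. Uncoupled RBPs are independent log-normal noise.
#'
#' @param config a [sim_config()].
#' @param truth a `SimTruth` (supplies the latent score).
#' @return list with `expr` (RBP x sample matrix) and `truth` (coupled ids
#'   and signs).
#' @export
simulate_rbp <- function(config, truth) {
  stop_if_not(inherits(config, "SimConfig"), "config must be a SimConfig")
  set.seed(derive_seed(config$seed, 3))
  s <- truth$latent_score
  n <- length(s)
  n_tot <- config$n_rbp_total; n_cpl <- config$n_rbp_coupled
  rbp_id <- sprintf("RBP%03d", seq_len(n_tot))
  n_pos <- ceiling(n_cpl / 2)
  sign_v <- c(rep(1, n_pos), rep(-1, n_cpl - n_pos))

  rho_s <- config$rbp_rho
  rho_p <- 2 * sin(pi * rho_s / 6)
  z <- qnorm(rank(s, ties.method = "average") / (n + 1))
  expr <- matrix(NA_real_, n_tot, n, dimnames = list(rbp_id, names(s)))
  for (k in seq_len(n_cpl)) {
    x <- rho_p * z + sqrt(1 - rho_p^2) * rnorm(n)
    expr[k, ] <- exp(2 + 0.8 * sign_v[k] * x)
  }
  if (n_cpl < n_tot) {
    expr[(n_cpl + 1):n_tot, ] <- matrix(
      rlnorm((n_tot - n_cpl) * n, meanlog = 2, sdlog = 0.8), ncol = n)
  }
  list(expr = expr,
       truth = list(coupled = rbp_id[seq_len(n_cpl)],
                    sign = setNames(sign_v, rbp_id[seq_len(n_cpl)])))
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

validate_iupac <- function(pattern) {
  letters_ <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters_, names(IUPAC_SETS))
  stop_if_not(length(bad) == 0, "invalid IUPAC letter(s): %s",
              paste(bad, collapse = ", "))
  letters_
}

# one concrete DNA realization of a degenerate IUPAC pattern
realize_motif <- function(pattern) {
  paste(vapply(validate_iupac(pattern), function(l) {
    set <- IUPAC_SETS[[l]]
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

random_seq <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate exon/intron flank sequences with planted motifs
#'
#' Background sequence is i.i.d. at a configurable GC content. For events
#' labeled with a motif's target role, one concrete realization of the
#' degenerate motif is planted per matching flank with probability
#' `motif_plant_rate`. The GC content of the window immediately upstream of
#' the 3' splice site (the tail of the upstream-intron flank) is lowered by
#' `gc_offset` for `"included"` events, emulating the lower upstream-3'SS GC
#' of included exons.
#'
#' @param config a [sim_config()].
#' @param event_roles named character vector (event id -> "included" /
#'   "excluded"); typically group-1 events are the "included" set.
#' @param motifs list of motif specs, each `list(pattern=, region=, role=)`
#'   with region in upstream_intron / exon / downstream_intron. Defaults:
#'   CYCUCY and CUBCCY in the intronic flanks of excluded exons, CYUCWKC in
#'   the exon body of included exons.
#' @param intron_len,exon_len flank lengths in nt.
#' @param background_gc background GC fraction.
#' @param gc_offset GC reduction applied to the included-set upstream window.
#' @param gc_window_len length of the 3'SS-upstream window.
#' @return list with `sequences` (data.frame: event_id, region, role,
#'   sequence) and `truth` (planted motif positions per sequence).
#' @export
simulate_sequences <- function(config, event_roles,
                               motifs = list(
                                 list(pattern = "CYCUCY", region = "upstream_intron", role = "excluded"),
                                 list(pattern = "CUBCCY", region = "downstream_intron", role = "excluded"),
                                 list(pattern = "CYUCWKC", region = "exon", role = "included")),
                               intron_len = 250, exon_len = 120,
                               background_gc = 0.45, gc_offset = 0.1,
                               gc_window_len = 100) {
  stop_if_not(inherits(config, "SimConfig"), "config must be a SimConfig")
  for (m in motifs) validate_iupac(m$pattern)
  set.seed(derive_seed(config$seed, 4))
  regions <- c("upstream_intron", "exon", "downstream_intron")
  ids <- names(event_roles)
  recs <- list(); planted <- list()
  for (i in seq_along(ids)) {
    role <- unname(event_roles[i])
    for (reg in regions) {
      len <- if (reg == "exon") exon_len else intron_len
      seq_ <- random_seq(len, background_gc)
      if (reg == "upstream_intron" && role == "included" && gc_offset != 0) {
        # regenerate the 3'SS-proximal window at reduced GC
        w <- min(gc_window_len, len)
        low <- random_seq(w, max(0, background_gc - gc_offset))
        substr(seq_, len - w + 1, len) <- low
      }
      for (m in motifs) {
        if (m$region == reg && m$role == role &&
            runif(1) < config$motif_plant_rate) {
          mot <- realize_motif(m$pattern)
          pos <- sample(len - nchar(mot) + 1, 1)
          substr(seq_, pos, pos + nchar(mot) - 1) <- mot
          planted[[paste(ids[i], reg, sep = "|")]] <- pos
        }
      }
      recs[[length(recs) + 1]] <- data.frame(event_id = ids[i], region = reg,
                                             role = role, sequence = seq_)
    }
  }
  seqs <- do.call(rbind, recs)
  rownames(seqs) <- NULL
  list(sequences = seqs, truth = list(planted = planted))
}

#' Write simulated flank sequences as FASTA
#' @param sequences the `sequences` data.frame from [simulate_sequences()].
#' @param path output FASTA path.
#' @export
write_flank_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences$sequence)
  names(x) <- paste(sequences$event_id, sequences$region, sequences$role,
                    sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
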