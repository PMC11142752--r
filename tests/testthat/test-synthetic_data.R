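test_that("SimConfig validates its invariants", {
  expect_error(sim_config(n_informative = 10, n_events = 5), "n_informative")
  expect_error(sim_config(psi_concentration = 0), "psi_concentration")
  expect_error(sim_config(latent_mixture = list(m1 = .5, m2 = .5, spread = 10)),
               "modes must differ")
  expect_error(sim_config(rbp_rho = 1), "rbp_rho")
  expect_error(sim_config(censor_rate = 1.2), "censor_rate")
})

test_that("same seed gives byte-identical bulk output", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_bulk(cfg); b <- simulate_bulk(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$true_psi, b$truth$true_psi)
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  write_junction_counts(a$counts, pa); write_junction_counts(b$counts, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
  # different seed differs
  expect_false(identical(simulate_bulk(tiny_config(seed = 12))$counts, a$counts))
})

test_that("zero-effect limit yields flat PSI columns at logistic(a_j)", {
  cfg <- tiny_config(seed = 5, coupling_strength = 0,
                     psi_concentration = 1e7, reads_per_event = 5000)
  sim <- simulate_bulk(cfg)
  a_j <- sim$truth$event_params$a
  expect_true(all(sim$truth$event_params$b == 0))
  sds <- apply(sim$truth$true_psi, 1, sd)
  expect_lt(max(sds), 1e-3)
  expect_equal(unname(rowMeans(sim$truth$true_psi)), plogis(a_j),
               tolerance = 1e-3)
})

test_that("generative means match the stated model (Monte-Carlo oracle)", {
  # spread -> large pins s_i at its mixture mode; then for informative events
  # E[psi_ij] = logistic(a_j + b_j * mode), by the Beta mean identity
  cfg <- sim_config(n_samples = 400, n_events = 40, n_informative = 20,
                    latent_mixture = list(m1 = 0.25, m2 = 0.75, spread = 2e6),
                    seed = 21)
  sim <- simulate_bulk(cfg)
  pars <- sim$truth$event_params
  mode2 <- sim$truth$cluster_label == 2
  g1 <- sim$truth$event_role == "group1"
  mc_mean <- rowMeans(sim$truth$true_psi[g1, mode2])
  expected <- plogis(pars$a[g1] + pars$b[g1] * 0.75)
  # Monte-Carlo tolerance: ~200 samples/event, Beta sd <= mu(1-mu)/sqrt(kappa)
  expect_equal(unname(mc_mean), unname(expected), tolerance = 0.02)
})

test_that("empirical PSI converges to truth and AS_true tracks the latent score", {
  cfg <- tiny_config(seed = 9, reads_per_event = 10000,
                     psi_concentration = 250, coupling_strength = 6)
  sim <- simulate_bulk(cfg)
  emp <- with(sim$counts, inc_count * 1 / (inc_count * 1 + skip_count * 2))
  truth_long <- sim$truth$true_psi[cbind(sim$counts$event_id,
                                         sim$counts$sample_id)]
  expect_lt(mean(abs(emp - truth_long), na.rm = TRUE), 0.01)
  rho <- cor(sim$truth$as_true, sim$truth$latent_score, method = "spearman")
  expect_gte(rho, 0.99)
})

test_that("survival generation hits the target censor rate and hazard direction", {
  cfg <- small_config(seed = 13)
  sim <- simulate_bulk(cfg)
  # binomial realization noise at n = 120: ~2 sd band around the target
  expect_lt(abs(mean(sim$metadata$status == 0) - cfg$censor_rate), 0.09)
  expect_true(all(sim$metadata$time > 0))
  # higher true AS score -> shorter event times on average
  ev <- sim$metadata$status == 1
  expect_lt(cor(sim$truth$as_true[ev], sim$metadata$time[ev],
                method = "spearman"), 0)
})

test_that("single-cell generator respects degenerate and Poisson regimes", {
  cfg <- tiny_config(seed = 2)
  bulk <- simulate_bulk(cfg)
  # degenerate coverage: no reads at all, annotation still emitted
  cfg0 <- tiny_config(seed = 2, sc_reads_per_cell_event = 0)
  sc0 <- simulate_sc(cfg0, bulk$truth)
  expect_equal(nrow(sc0$counts), 0)
  expect_gt(nrow(sc0$annotation), 0)
  expect_error(simulate_sc(tiny_config(sc_states = character()), bulk$truth),
               "state")

  # Poisson-sum oracle: lambda=2, 100 cells => pseudobulk total ~ 200 +- 3 SD
  cfg2 <- sim_config(n_samples = 20, n_events = 50, n_informative = 10,
                     sc_n_patients = 1, sc_states = "stateA",
                     sc_cells_per_state = 100, sc_reads_per_cell_event = 2,
                     seed = 4)
  bulk2 <- simulate_bulk(cfg2)
  sc2 <- simulate_sc(cfg2, bulk2$truth)
  tot <- tapply(sc2$counts$inc_count + sc2$counts$skip_count,
                sc2$counts$event_id, sum)
  lam_sum <- 2 * 100
  expect_true(all(abs(tot - lam_sum) < 3 * sqrt(lam_sum) + 1e-9))
})

test_that("state-structured truth separates pseudobulk PSI at high coverage", {
  cfg <- sim_config(n_samples = 20, n_events = 80, n_informative = 40,
                    coupling_strength = 10, psi_concentration = 500,
                    sc_n_patients = 2, sc_states = c("hi", "lo"),
                    sc_cells_per_state = 60, sc_reads_per_cell_event = 50,
                    seed = 8)
  bulk <- simulate_bulk(cfg)
  sc <- simulate_sc(cfg, bulk$truth)
  pb <- aggregate_pseudobulk(sc$counts, sc$annotation)
  x <- pseudobulk_psi(pb, bulk$events)
  tp <- sc$truth$true_psi
  # wherever planted separation is extreme, estimates separate strongly
  for (pat in names(sc$truth$patient_score)) {
    hi <- paste0(pat, ":hi"); lo <- paste0(pat, ":lo")
    big <- which(abs(tp[, hi] - tp[, lo]) > 0.75)
    big <- big[x$detected[big, hi] & x$detected[big, lo]]
    if (length(big) == 0) next
    est_sep <- abs(x$psi[big, hi] - x$psi[big, lo])
    expect_gt(min(est_sep), 0.6)
  }
})

test_that("RBP generator hits the target Spearman correlation and sign bookkeeping", {
  cfg <- sim_config(n_samples = 500, n_events = 20, n_informative = 10,
                    n_rbp_total = 60, n_rbp_coupled = 29, rbp_rho = 0.8,
                    seed = 6)
  sim <- simulate_bulk(cfg)
  rbp <- simulate_rbp(cfg, sim$truth)
  expect_length(rbp$truth$coupled, 29)
  expect_equal(sum(rbp$truth$sign > 0), ceiling(29 / 2))
  s <- sim$truth$latent_score
  rho <- vapply(rbp$truth$coupled, function(r)
    cor(rbp$expr[r, names(s)], s, method = "spearman"), numeric(1))
  expect_gte(mean(abs(abs(rho) * sign(rbp$truth$sign) * sign(rho) - 0.8) <= 0.07),
             0.95)
  expect_true(all(sign(rho) == rbp$truth$sign))

  # null case: rho = 0 makes "coupled" RBPs indistinguishable from noise
  cfg0 <- sim_config(n_samples = 200, n_events = 20, n_informative = 10,
                     n_rbp_total = 60, n_rbp_coupled = 20, rbp_rho = 0,
                     seed = 7)
  sim0 <- simulate_bulk(cfg0)
  rbp0 <- simulate_rbp(cfg0, sim0$truth)
  s0 <- sim0$truth$latent_score
  rho0 <- vapply(rownames(rbp0$expr), function(r)
    cor(rbp0$expr[r, names(s0)], s0, method = "spearman"), numeric(1))
  band <- quantile(abs(rho0[setdiff(names(rho0), rbp0$truth$coupled)]), 0.95)
  expect_gte(mean(abs(rho0[rbp0$truth$coupled]) <= band + 0.02), 0.9)
})

test_that("sequence generator plants motifs and GC offsets as configured", {
  roles <- setNames(rep(c("included", "excluded"), each = 150),
                    sprintf("EV%04d", 1:300))
  cfg <- tiny_config(seed = 10, motif_plant_rate = 1)
  sq <- simulate_sequences(cfg, roles)
  up <- sq$sequences[sq$sequences$region == "upstream_intron", ]
  exc <- up$sequence[up$role == "excluded"]
  expect_true(all(iupac_match("CYCUCY", exc)))

  # planted GC offset of -0.1 recovered within +-0.02 at n = 150/set
  inc <- up$sequence[up$role == "included"]
  gc <- gc_profile(inc, exc, window_len = 100)
  expect_lt(abs(gc$diff - (-0.1)), 0.02)

  # plant rate 0: no enrichment (typical run)
  cfg0 <- tiny_config(seed = 10, motif_plant_rate = 0)
  sq0 <- simulate_sequences(cfg0, roles, gc_offset = 0)
  up0 <- sq0$sequences[sq0$sequences$region == "upstream_intron", ]
  en0 <- motif_enrichment(up0$sequence[up0$role == "excluded"],
                          up0$sequence[up0$role == "included"], "CYCUCY")
  expect_gt(en0$p, 0.01)

  expect_error(simulate_sequences(cfg, roles,
                                  motifs = list(list(pattern = "CXC",
                                                     region = "exon",
                                                     role = "included"))),
               "invalid IUPAC")
})
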