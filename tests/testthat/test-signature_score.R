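test_that("a perfectly separating event outranks pure-noise events", {
  set.seed(12)
  n <- 60
  m <- matrix(runif(50 * n), 50, n,
              dimnames = list(sprintf("EV%03d", 1:50), sprintf("S%03d", 1:n)))
  labels <- setNames(rep(1:2, each = n / 2), colnames(m))
  m["EV025", ] <- ifelse(labels == 1, runif(n, 0, 0.4), runif(n, 0.6, 1))
  model <- rank_events_by_mdg(make_psimatrix(m), labels, n_trees = 100, seed = 5)
  expect_equal(names(model$importance)[1], "EV025")
  expect_true(all(model$importance >= 0))
  expect_error(rank_events_by_mdg(make_psimatrix(m), setNames(rep(1, n),
                                                              colnames(m))),
               "two classes")
})

test_that("MDG recovers planted informative events (scaled)", {
  cfg <- small_config(seed = 23)
  sim <- simulate_bulk(cfg)
  x <- build_psi_matrix(sim$counts, sim$events)
  # faithful pipeline: rank against *discovered* clusters of representatives
  res <- consensus_cluster(x, k = 2, n_iter = 40, seed = 7)
  reps <- select_representatives(res, length(res$labels))
  model <- rank_events_by_mdg(subset_psi(x, samples = reps), res$labels,
                              n_select = cfg$n_informative,
                              n_trees = 800, seed = 3)
  informative <- names(sim$truth$event_role)[sim$truth$event_role != "noise"]
  precision <- mean(model$selected_events %in% informative)
  expect_gte(precision, 0.9)
})

test_that("label permutation collapses planted-event importance", {
  cfg <- tiny_config(seed = 29)
  sim <- simulate_bulk(cfg)
  x <- build_psi_matrix(sim$counts, sim$events)
  labels <- sim$truth$cluster_label
  real <- rank_events_by_mdg(x, labels, n_trees = 100, seed = 3)$importance
  set.seed(77)
  null_mdg <- replicate(20, {
    perm <- setNames(sample(labels), names(labels))
    rank_events_by_mdg(x, perm, n_trees = 100, seed = 3)$importance[names(real)]
  })
  # per-event null: an informative event's true-label importance should
  # exceed the 95th percentile of its own permutation distribution
  thr <- apply(null_mdg, 1, quantile, 0.95)
  informative <- names(sim$truth$event_role)[sim$truth$event_role != "noise"]
  expect_gte(mean(real[informative] > thr[informative]), 0.9)
})

test_that("group assignment follows the worse-survival direction rule", {
  # two clusters with hand-made survival: cluster 2 dies early
  smp <- sprintf("S%02d", 1:40)
  labels <- setNames(rep(1:2, each = 20), smp)
  surv <- data.frame(sample_id = smp,
                     time = c(rexp(20, 1 / 2000), rexp(20, 1 / 200)) + 1,
                     status = 1)
  psi <- matrix(0.5, 4, 40, dimnames = list(c("up", "down", "flat", "weak"), smp))
  psi["up", labels == 2] <- 0.8; psi["up", labels == 1] <- 0.3
  psi["down", labels == 2] <- 0.2; psi["down", labels == 1] <- 0.7
  psi["weak", labels == 2] <- 0.52; psi["weak", labels == 1] <- 0.5
  x <- make_psimatrix(psi)
  model <- structure(list(importance = c(up = 3, down = 2.5, flat = 1, weak = 0.5),
                          selected_events = c("up", "down", "flat", "weak")),
                     class = "SignatureModel")
  fit <- assign_groups(x, model, labels, surv, n_per_group = 2)
  # fewer candidates than requested: retained with a warning per short group
  w <- testthat::capture_warnings(
    assign_groups(x, model, labels, surv, n_per_group = 3))
  expect_match(w, "candidate events", all = TRUE)
  expect_length(w, 2)
  expect_equal(fit$worse_cluster, 2)
  expect_true("up" %in% fit$group1)
  expect_true("down" %in% fit$group2)
  expect_true("weak" %in% fit$group1) # mean PSI higher in worse cluster
  expect_lt(fit$logrank_p, 0.01)
})

test_that("group assignment recovers planted couplings (scaled)", {
  cfg <- small_config(seed = 37)
  sim <- simulate_bulk(cfg)
  x <- build_psi_matrix(sim$counts, sim$events)
  model <- rank_events_by_mdg(x, sim$truth$cluster_label, n_select = 50,
                              n_trees = 200, seed = 3)
  model <- assign_groups(x, model, sim$truth$cluster_label, sim$metadata,
                         n_per_group = 20)
  b <- setNames(sim$truth$event_params$b, sim$truth$event_params$event_id)
  # worse survival comes from high AS_true = high latent score; group-1
  # events must be the positively coupled ones
  expect_gte(sum(b[model$group1] > 0), 18)
  expect_gte(sum(b[model$group2] < 0), 18)
})

test_that("AS score is the difference of group means with detection guards", {
  smp <- c("A", "B", "C")
  psi <- rbind(g1a = c(1, 0.5, 0.25), g1b = c(1, 0.7, NA),
               g2a = c(0, 0.5, 0.5), g2b = c(0, 0.3, 0.75))
  colnames(psi) <- smp
  x <- make_psimatrix(psi)
  model <- structure(list(importance = setNames(4:1, rownames(psi)),
                          selected_events = rownames(psi),
                          group1 = c("g1a", "g1b"), group2 = c("g2a", "g2b")),
                     class = "SignatureModel")
  sc <- as_score(x, model, min_detected = 2)
  expect_equal(sc$as_score[sc$sample_id == "A"], 1) # extreme case
  expect_equal(sc$as_score[sc$sample_id == "B"], 0.2, tolerance = 1e-12)
  expect_true(is.na(sc$as_score[sc$sample_id == "C"])) # only 1 g1 detected
  sc1 <- as_score(x, model, min_detected = 1)
  expect_equal(sc1$as_score[sc1$sample_id == "C"], 0.25 - 0.625, tolerance = 1e-12)

  # hand-computed arithmetic oracle on a 40-event random table
  set.seed(9)
  psi40 <- matrix(runif(40 * 5), 40, 5,
                  dimnames = list(sprintf("E%02d", 1:40), sprintf("S%d", 1:5)))
  model40 <- structure(list(group1 = sprintf("E%02d", 1:20),
                            group2 = sprintf("E%02d", 21:40)),
                       class = "SignatureModel")
  sc40 <- as_score(make_psimatrix(psi40), model40, min_detected = 10)
  by_hand <- colMeans(psi40[1:20, ]) - colMeans(psi40[21:40, ])
  expect_equal(sc40$as_score, unname(by_hand), tolerance = 1e-12)
})

test_that("AS score is bounded, monotone and order-invariant", {
  set.seed(31)
  psi <- matrix(runif(40 * 8), 40, 8,
                dimnames = list(sprintf("E%02d", 1:40), sprintf("S%d", 1:8)))
  model <- structure(list(group1 = sprintf("E%02d", 1:20),
                          group2 = sprintf("E%02d", 21:40)),
                     class = "SignatureModel")
  x <- make_psimatrix(psi)
  sc <- as_score(x, model, min_detected = 10)$as_score
  expect_true(all(sc >= -1 & sc <= 1))
  # strictly increasing in any group-1 PSI
  psi2 <- psi; psi2["E01", 1] <- min(1, psi2["E01", 1] + 0.1)
  sc2 <- as_score(make_psimatrix(psi2), model, min_detected = 10)$as_score
  expect_gt(sc2[1], sc[1])
  # strictly decreasing in any group-2 PSI
  psi3 <- psi; psi3["E40", 1] <- min(1, psi3["E40", 1] + 0.1)
  sc3 <- as_score(make_psimatrix(psi3), model, min_detected = 10)$as_score
  expect_lt(sc3[1], sc[1])
  # event/sample order invariance; no refitting at scoring time
  perm <- make_psimatrix(psi[sample(40), sample(8)])
  scp <- as_score(perm, model, min_detected = 10)
  expect_equal(setNames(scp$as_score, scp$sample_id)[colnames(psi)],
               setNames(sc, colnames(psi)))
})

test_that("signature model serialization round-trips", {
  model <- structure(list(importance = c(a = 3, b = 2, c = 1, d = 0.5),
                          selected_events = c("a", "b", "c", "d"),
                          group1 = "a", group2 = "b"),
                     class = "SignatureModel")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_model(model, path)
  back <- read_signature_model(path)
  expect_equal(back$group1, "a")
  expect_equal(back$group2, "b")
  expect_equal(unname(back$importance[back$selected_events]),
               unname(model$importance[model$selected_events]))
})
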