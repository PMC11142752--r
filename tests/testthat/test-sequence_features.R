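test_that("IUPAC matcher agrees with the regex oracle on random pairs", {
  set.seed(3)
  letters_ <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
  for (i in 1:40) {
    pat <- paste(sample(letters_, sample(3:7, 1), replace = TRUE), collapse = "")
    seqs <- vapply(1:25, function(j)
      paste(sample(c("A", "C", "G", "T"), sample(5:30, 1), replace = TRUE),
            collapse = ""), character(1))
    expect_identical(iupac_match(pat, seqs), iupac_regex_oracle(pat, seqs))
  }
  expect_error(iupac_match("CXC", "ACGT"), "invalid IUPAC")
  # U/T equivalence on both sides
  expect_true(iupac_match("CYCUCY", "AACTCTCTAA"))
  expect_true(iupac_match("CYCTCY", "AACUCUCUAA"))
})

test_that("GC window profiling handles boundaries and short sequences", {
  out <- gc_profile(c("GGCC", "GCGC"), c("ATAT", "TATA"), window_len = 4)
  expect_equal(out$gc_a, c(1, 1))
  expect_equal(out$gc_b, c(0, 0))
  expect_equal(out$diff, 1)
  # short sequences excluded and counted
  out2 <- gc_profile(c("GGCC", "GC"), c("ATAT"), window_len = 4)
  expect_equal(out2$n_excluded, 1)
  # identical sets: difference exactly 0
  s <- c("ACGTACGTAA", "GGGTTTACGT")
  expect_equal(gc_profile(s, s, window_len = 8)$diff, 0)
})

test_that("splice-site models score as specified", {
  set.seed(11)
  train <- c("AGGTAAGTA", "AGGTGAGTA", "CGGTAAGTG", "AGGTAAGAA", "TGGTAAGTA")
  q <- c(A = .25, C = .25, G = .25, T = .25)

  wmm <- train_splice_model(train, "WMM", background = q)
  # uniform trained model scores 0 everywhere (log-odds identity)
  uni <- wmm; uni$pwm[] <- 0.25
  expect_equal(score_splice_site(c("ACGTACGTA", "GGGGGGGGG"), uni), c(0, 0))
  # consensus sequence attains the maximal WMM score
  consensus <- paste(rownames(wmm$pwm)[apply(wmm$pwm, 2, which.max)],
                     collapse = "")
  sc_cons <- score_splice_site(consensus, wmm)
  rand <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""),
    character(1))
  expect_true(all(score_splice_site(rand, wmm) <= sc_cons + 1e-12))
  # WMM equals the per-position table-lookup oracle
  mers <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""),
    character(1))
  expect_equal(score_splice_site(mers, wmm),
               vapply(mers, wmm_score_oracle, numeric(1), wmm$pwm,
                      wmm$background, USE.NAMES = FALSE),
               tolerance = 1e-9)

  # all three models rank a strong-site fixture above its scrambled version
  strong <- "AGGTAAGTA"
  scrambled <- "TAAGAGGAT"
  for (kind in c("WMM", "MM1", "DINUC")) {
    mod <- train_splice_model(train, kind, background = q)
    expect_gt(score_splice_site(strong, mod), score_splice_site(scrambled, mod))
  }
  expect_error(score_splice_site("ACGT", wmm), "length")
  expect_error(score_splice_site("ACGTACGTN", wmm), "unseen symbol")
})

test_that("motif enrichment counts presence and applies Haldane correction", {
  withA <- c("AACCCTCCAA", "TTCTCTCTTT", "GGGGAAAATT")
  noHit <- c("AAAAAAAAAA", "GGGGGGGGGG")
  en <- motif_enrichment(withA, noHit, "CYCUCY")
  expect_equal(en$table["present", "set_a"], 2) # only 2 contain CYCUCY
  expect_gt(en$odds_ratio, 1)
  # motif absent from both sets: OR via Haldane, p = 1
  none <- motif_enrichment(noHit, noHit, "CYCUCY")
  expect_equal(none$p, 1)
  expect_equal(none$odds_ratio, 1)
  # swapping set labels inverts the odds ratio
  sw <- motif_enrichment(noHit, withA, "CYCUCY")
  expect_equal(sw$odds_ratio, 1 / en$odds_ratio, tolerance = 1e-12)
  expect_error(motif_enrichment(character(), withA, "CYC"), "non-empty")
})

test_that("planted motif enrichment is detected with power", {
  set.seed(21)
  mk_set <- function(n, plant_prob) {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
      if (runif(1) < plant_prob) {
        mot <- gsub("Y", sample(c("C", "T"), 1), "CYCTCY")
        mot <- sub("Y", sample(c("C", "T"), 1), mot)
        pos <- sample(55, 1)
        substr(s, pos, pos + 5) <- mot
      }
      s
    }, character(1))
  }
  en <- motif_enrichment(mk_set(500, 0.6), mk_set(500, 0), "CYCUCY")
  expect_lt(en$p, 1e-4)
  expect_gt(en$odds_ratio, 1)
})

test_that("de novo k-mer table ranks a planted hexamer first", {
  set.seed(31)
  bg <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
    character(1))
  set_a <- bg(300); set_b <- bg(300)
  plant <- "CTCTCT"
  idx <- sample(300, 240)
  for (i in idx) {
    pos <- sample(45, 1)
    substr(set_a[i], pos, pos + 5) <- plant
  }
  tab <- denovo_kmers(set_a, set_b, k = 6)
  # the planted hexamer (or an overlapping neighbor) ranks first
  top <- tab$kmer[1]
  overlap_ok <- function(k1, k2) {
    any(vapply(1:5, function(sh)
      substr(k1, sh + 1, 6) == substr(k2, 1, 6 - sh) ||
        substr(k2, sh + 1, 6) == substr(k1, 1, 6 - sh), logical(1)))
  }
  expect_true(top == plant || overlap_ok(top, plant))
  expect_lt(tab$q[tab$kmer == plant], 0.001)
  # identical sets: nothing significant (typical run)
  null_tab <- denovo_kmers(set_b, set_b, k = 6)
  expect_true(all(null_tab$q > 0.05))
  # k longer than all sequences: empty table
  expect_equal(nrow(denovo_kmers(set_a, set_b, k = 60)), 0)
})

test_that("flank FASTA round-trips through Biostrings", {
  cfg <- tiny_config(seed = 10)
  roles <- setNames(rep(c("included", "excluded"), 10), sprintf("E%02d", 1:20))
  sq <- simulate_sequences(cfg, roles)
  path <- withr::local_tempfile(fileext = ".fa")
  write_flank_fasta(sq$sequences, path)
  back <- read_flank_fasta(path)
  expect_equal(nrow(back), nrow(sq$sequences))
  expect_equal(back$sequence, sq$sequences$sequence)
  expect_equal(back$role, sq$sequences$role)
})
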