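#' Match a degenerate IUPAC motif in sequences
#'
#' Presence/absence of at least one match of an IUPAC pattern (RNA `U` and
#' DNA `T` are equivalent on both sides) in each sequence, via fixed-width
#' degenerate matching.
#'
#' @param pattern IUPAC string over A C G T/U R Y S W K M B D H V N.
#' @param sequences character vector of A/C/G/T/U sequences.
#' @return Logical vector, one entry per sequence.
#' @export
iupac_match <- function(pattern, sequences) {
  validate_iupac(pattern)
  pat <- chartr("U", "T", toupper(pattern))
  seqs <- chartr("U", "T", toupper(sequences))
  if (any(nchar(seqs) < nchar(pat))) {
    # short sequences simply cannot match
  }
  subj <- Biostrings::DNAStringSet(seqs)
  Biostrings::vcountPattern(pat, subj, fixed = FALSE) > 0
}

#' GC-content profile upstream of the 3' splice site
#'
#' Computes the GC fraction of the window immediately upstream of the 3'SS
#' (the last `window_len` nt of each upstream-intron flank) for two sequence
#' sets and compares them with a Wilcoxon rank-sum test. Sequences shorter
#' than the window are excluded and counted.
#'
#' @param set_a,set_b character vectors of upstream-intron flank sequences
#'   (e.g. included-exon vs excluded-exon events).
#' @param window_len window length in nt (default 100).
#' @return list with per-set GC vectors `gc_a`, `gc_b`, `diff`
#'   (mean GC of set A minus set B), `p` (rank-sum), and `n_excluded`.
#' @export
gc_profile <- function(set_a, set_b, window_len = 100) {
  window_gc <- function(seqs) {
    keep <- nchar(seqs) >= window_len
    wins <- substr(seqs[keep], nchar(seqs[keep]) - window_len + 1,
                   nchar(seqs[keep]))
    gc <- vapply(strsplit(chartr("U", "T", toupper(wins)), ""), function(ch)
      mean(ch %in% c("G", "C")), numeric(1))
    list(gc = gc, excluded = sum(!keep))
  }
  a <- window_gc(set_a); b <- window_gc(set_b)
  stop_if_not(length(a$gc) > 0 && length(b$gc) > 0,
              "no sequences long enough for the window")
  p <- suppressWarnings(wilcox.test(a$gc, b$gc)$p.value)
  list(gc_a = a$gc, gc_b = b$gc, diff = mean(a$gc) - mean(b$gc), p = p,
       n_excluded = a$excluded + b$excluded)
}

BASES <- c("A", "C", "G", "T")

seq_to_rows <- function(seqs, L) {
  seqs <- chartr("U", "T", toupper(seqs))
  stop_if_not(all(nchar(seqs) == L), "sequence length must equal model window")
  mat <- do.call(rbind, strsplit(seqs, ""))
  bad <- setdiff(unique(as.vector(mat)), BASES)
  stop_if_not(length(bad) == 0, "unseen symbol(s): %s", paste(bad, collapse = ", "))
  mat
}

#' Train a splice-site strength model
#'
#' Three log-odds scoring models over a fixed window (MaxEntScan-convention
#' windows: 9-mer for 5'SS, 23-mer for 3'SS), trained from annotated-site
#' sequences with a 0.5 pseudocount per base against an i.i.d. background:
#' \itemize{
#'   \item `WMM` — position weight matrix: independent per-position base
#'     probabilities;
#'   \item `MM1` — inhomogeneous first-order Markov chain: position-1
#'     marginal plus per-position transition probabilities;
#'   \item `DINUC` — position-independent dinucleotide composition.
#' }
#'
#' @param seqs training sequences of identical length.
#' @param kind one of `"WMM"`, `"MM1"`, `"DINUC"`.
#' @param background named base-probability vector (default uniform).
#' @param pseudocount added per cell during training (default 0.5).
#' @return A `SpliceSiteModel` list with the trained probabilities.
#' @export
train_splice_model <- function(seqs, kind = c("WMM", "MM1", "DINUC"),
                               background = c(A = .25, C = .25, G = .25, T = .25),
                               pseudocount = 0.5) {
  kind <- match.arg(kind)
  L <- nchar(seqs[1])
  mat <- seq_to_rows(seqs, L)
  n <- nrow(mat)
  pos_probs <- function(col) {
    cnt <- table(factor(col, levels = BASES)) + pseudocount
    as.numeric(cnt / sum(cnt))
  }
  model <- list(kind = kind, L = L, background = background[BASES])
  if (kind == "WMM") {
    model$pwm <- vapply(seq_len(L), function(j) pos_probs(mat[, j]),
                        numeric(4))
    rownames(model$pwm) <- BASES
  } else if (kind == "MM1") {
    model$p1 <- setNames(pos_probs(mat[, 1]), BASES)
    model$trans <- lapply(2:L, function(j) {
      tab <- table(factor(mat[, j - 1], levels = BASES),
                   factor(mat[, j], levels = BASES)) + pseudocount
      sweep(tab, 1, rowSums(tab), "/")
    })
  } else {
    di <- paste0(rep(BASES, each = 4), rep(BASES, 4))
    obs <- as.vector(vapply(seq_len(L - 1), function(j)
      paste0(mat[, j], mat[, j + 1]), character(n)))
    cnt <- table(factor(obs, levels = di)) + pseudocount
    model$dinuc <- setNames(as.numeric(cnt / sum(cnt)), di)
  }
  structure(model, class = "SpliceSiteModel")
}

#' Score a sequence under a splice-site model
#'
#' Log2-odds of the sequence under the trained model versus the i.i.d.
#' background. For `DINUC` the background of a dinucleotide is the product
#' of its base probabilities.
#'
#' @param seqs character vector of sequences, each of the model's window
#'   length.
#' @param model a [train_splice_model()] result.
#' @return Numeric vector of scores (bits).
#' @export
score_splice_site <- function(seqs, model) {
  stop_if_not(inherits(model, "SpliceSiteModel"), "model must be a SpliceSiteModel")
  mat <- seq_to_rows(seqs, model$L)
  q <- model$background
  n <- nrow(mat)
  if (model$kind == "WMM") {
    sc <- rowSums(matrix(vapply(seq_len(model$L), function(j)
      log2(model$pwm[mat[, j], j] / q[mat[, j]]), numeric(n)), nrow = n))
  } else if (model$kind == "MM1") {
    sc <- log2(model$p1[mat[, 1]] / q[mat[, 1]])
    for (j in 2:model$L) {
      tr <- model$trans[[j - 1]]
      sc <- sc + log2(tr[cbind(mat[, j - 1], mat[, j])] / q[mat[, j]])
    }
  } else {
    sc <- rowSums(matrix(vapply(seq_len(model$L - 1), function(j) {
      di <- paste0(mat[, j], mat[, j + 1])
      log2(model$dinuc[di] / (q[mat[, j]] * q[mat[, j + 1]]))
    }, numeric(n)), nrow = n))
  }
  unname(sc)
}

haldane_or <- function(a, b, c_, d_) {
  if (any(c(a, b, c_, d_) == 0)) { a <- a + .5; b <- b + .5; c_ <- c_ + .5; d_ <- d_ + .5 }
  (a * d_) / (b * c_)
}

#' Degenerate-motif enrichment between two sequence sets
#'
#' Per-sequence presence/absence of at least one IUPAC match (not occurrence
#' counts, avoiding length confounding), compared between sets with Fisher's
#' exact test. The odds ratio uses the Haldane 0.5 correction when any cell
#' is zero.
#'
#' @param set_a,set_b non-empty character vectors of sequences.
#' @param pattern IUPAC motif.
#' @return list with the 2x2 `table`, `odds_ratio`, `p`.
#' @export
motif_enrichment <- function(set_a, set_b, pattern) {
  stop_if_not(length(set_a) > 0 && length(set_b) > 0, "both sets must be non-empty")
  stop_if_not(nchar(pattern) <= max(nchar(c(set_a, set_b))),
              "motif longer than every sequence")
  hit_a <- sum(iupac_match(pattern, set_a))
  hit_b <- sum(iupac_match(pattern, set_b))
  tab <- matrix(c(hit_a, length(set_a) - hit_a,
                  hit_b, length(set_b) - hit_b), 2, 2,
                dimnames = list(c("present", "absent"), c("set_a", "set_b")))
  p <- fisher.test(tab)$p.value
  list(table = tab, odds_ratio = haldane_or(tab[1, 1], tab[2, 1],
                                            tab[1, 2], tab[2, 2]), p = p)
}

#' De novo k-mer enrichment between two sequence sets
#'
#' Per-sequence presence counts of every observed k-mer in each set,
#' Fisher exact p per k-mer with BH adjustment, ranked by q then descending
#' odds ratio.
#'
#' @param set_a,set_b character vectors of sequences.
#' @param k k-mer length (default 6); if `k` exceeds every sequence length
#'   an empty table is returned.
#' @return data.frame with `kmer`, `n_a`, `n_b`, `odds_ratio`, `p`, `q`,
#'   sorted by rank.
#' @export
denovo_kmers <- function(set_a, set_b, k = 6) {
  empty <- data.frame(kmer = character(), n_a = integer(), n_b = integer(),
                      odds_ratio = numeric(), p = numeric(), q = numeric())
  if (k > max(nchar(c(set_a, set_b)))) return(empty)
  presence <- function(seqs) {
    seqs <- seqs[nchar(seqs) >= k]
    x <- Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs)))
    occ <- Biostrings::oligonucleotideFrequency(x, width = k)
    colSums(occ > 0)
  }
  pa <- presence(set_a); pb <- presence(set_b)
  na <- sum(nchar(set_a) >= k); nb <- sum(nchar(set_b) >= k)
  keep <- which(pa + pb > 0)
  if (length(keep) == 0) return(empty)
  out <- data.frame(kmer = names(pa)[keep],
                    n_a = unname(pa[keep]), n_b = unname(pb[keep]))
  out$odds_ratio <- mapply(haldane_or, out$n_a, na - out$n_a,
                           out$n_b, nb - out$n_b)
  out$p <- vapply(seq_len(nrow(out)), function(i)
    fisher.test(matrix(c(out$n_a[i], na - out$n_a[i],
                         out$n_b[i], nb - out$n_b[i]), 2, 2))$p.value,
    numeric(1))
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, -out$odds_ratio, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Read flank sequences from FASTA
#'
#' Reads a FASTA written by [write_flank_fasta()] (headers
#' `event_id|region|role`); `U` is normalized to `T` at ingestion.
#'
#' @param path FASTA path.
#' @return data.frame with `event_id`, `region`, `role`, `sequence`.
#' @export
read_flank_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  stop_if_not(all(lengths(parts) == 3),
              "FASTA headers must be event_id|region|role")
  data.frame(event_id = vapply(parts, `[`, "", 1),
             region = vapply(parts, `[`, "", 2),
             role = vapply(parts, `[`, "", 3),
             sequence = chartr("U", "T", toupper(as.character(x))))
}
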