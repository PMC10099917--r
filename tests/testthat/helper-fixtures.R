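# Shared fixtures and independent oracles for the test suite.

# Random alignment fixture: i.i.d. cells, optional missing fraction, with a
# per-taxon guarantee of at least one observed cell.
random_alignment <- function(n, p, alphabet = dna_alphabet(), seed = 1,
                             gap_fraction = 0, freqs = NULL) {
  set.seed(seed)
  states <- alphabet$states
  if (is.null(freqs)) freqs <- rep(1 / length(states), length(states))
  mat <- matrix(sample(states, n * p, replace = TRUE, prob = freqs),
                nrow = n, dimnames = list(paste0("t", seq_len(n)), NULL))
  if (gap_fraction > 0) {
    k <- round(gap_fraction * n * p)
    keep_one <- cbind(seq_len(n), sample.int(p, n, replace = TRUE))
    protected <- (keep_one[, 2L] - 1L) * n + keep_one[, 1L]
    pool <- setdiff(seq_len(n * p), protected)
    mat[sample(pool, min(k, length(pool)))] <- NA_character_
  }
  new_alignment(mat, alphabet)
}

# Deliberately heterogeneous fixture: two blocks of taxa with different
# compositions, built from exact counts (no sampling noise).
heterogeneous_alignment <- function(n = 4, counts1 = c(4, 2, 2, 2),
                                    counts2 = c(1, 3, 3, 3),
                                    alphabet = dna_alphabet()) {
  states <- alphabet$states
  row_of <- function(cn) rep(states, times = cn)
  mat <- rbind(
    do.call(rbind, replicate(ceiling(n / 2), row_of(counts1), simplify = FALSE)),
    do.call(rbind, replicate(floor(n / 2), row_of(counts2), simplify = FALSE)))
  rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  new_alignment(mat, alphabet)
}

# Independent oracle: character-by-character double-loop tally and metric
# evaluation, written directly from the metric definitions and kept free of
# the package's vectorized implementation.
naive_frequencies <- function(aln) {
  states <- alignment_alphabet(aln)$states
  n <- nrow(aln)
  freqs <- matrix(0, n, length(states),
                  dimnames = list(rownames(aln), states))
  eff <- integer(n)
  for (i in seq_len(n)) {
    for (jj in seq_len(ncol(aln))) {
      ch <- aln[i, jj]
      if (!is.na(ch)) {
        eff[i] <- eff[i] + 1L
        freqs[i, ch] <- freqs[i, ch] + 1
      }
    }
    freqs[i, ] <- freqs[i, ] / eff[i]
  }
  mean_freqs <- rep(0, length(states))
  for (j in seq_along(states)) {
    for (i in seq_len(n)) mean_freqs[j] <- mean_freqs[j] + freqs[i, j]
    mean_freqs[j] <- mean_freqs[j] / n
  }
  list(freqs = freqs, mean_freqs = stats::setNames(mean_freqs, states),
       effective_lengths = eff)
}

naive_rcfv <- function(aln) {
  nf <- naive_frequencies(aln)
  states <- colnames(nf$freqs)
  n <- nrow(nf$freqs)
  total <- 0
  cs <- stats::setNames(rep(0, length(states)), states)
  ts <- stats::setNames(rep(0, n), rownames(nf$freqs))
  for (i in seq_len(n)) {
    for (j in seq_along(states)) {
      term <- abs(nf$freqs[i, j] - nf$mean_freqs[[j]]) / n
      total <- total + term
      cs[j] <- cs[j] + term
      ts[i] <- ts[i] + term
    }
  }
  list(total = total, cs = cs, ts = ts)
}

# Write a small FASTA file from name -> sequence-string pairs.
write_raw_fasta <- function(named_seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(named_seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(named_seqs[[nm]], con)
  }
  path
}
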