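#' Per-taxon character-state frequencies
#'
#' Tallies the occurrences \eqn{O_{ij}} of each canonical state \eqn{j} per
#' taxon \eqn{i}, with missing cells excluded, and derives relative
#' frequencies \eqn{\mu_{ij} = O_{ij} / L_i} (where \eqn{L_i} is the taxon's
#' non-missing cell count) and dataset-mean frequencies
#' \eqn{\bar\mu_j = \sum_i \mu_{ij} / n}. Excluding missing cells from the
#' denominator is what makes the downstream metrics robust to gaps: a taxon's
#' composition is estimated from the residues it actually has. For
#' complete-data alignments this reduces to \eqn{O_{ij} / p}. The dataset
#' mean is the unweighted mean of per-taxon frequencies, not the pooled
#' residue frequency; the two differ when effective lengths differ.
#'
#' @param aln an `rcfv_alignment`.
#' @return An object of class `rcfv_freqtab`: a list with `counts` and
#'   `freqs` (taxa x states matrices), `mean_freqs`, `effective_lengths`,
#'   `n_taxa`, `n_columns`, `alphabet`.
#' @export
tabulate_frequencies <- function(aln) {
  alphabet <- alignment_alphabet(aln)
  states <- alphabet$states
  m <- length(states)
  n <- nrow(aln); p <- ncol(aln)
  codes <- match(unclass(aln), states)        # column-major, NA = missing
  keep <- which(!is.na(codes))
  row_idx <- ((keep - 1L) %% n) + 1L
  counts <- matrix(tabulate((row_idx - 1L) * m + codes[keep], nbins = n * m),
                   nrow = n, ncol = m, byrow = TRUE,
                   dimnames = list(rownames(aln), states))
  eff <- rowSums(counts)
  if (any(eff == 0L))
    stop(sprintf("taxon '%s' has no non-missing cells",
                 rownames(aln)[which(eff == 0L)[1L]]))
  freqs <- counts / eff
  structure(
    list(counts = counts, freqs = freqs,
         mean_freqs = colMeans(freqs),
         effective_lengths = eff,
         n_taxa = n, n_columns = p, alphabet = alphabet),
    class = "rcfv_freqtab")
}

#' @export
print.rcfv_freqtab <- function(x, ...) {
  cat(sprintf("<frequency table: %d taxa x %d states (alphabet '%s'), p = %d>\n",
              x$n_taxa, length(x$alphabet$states), x$alphabet$name, x$n_columns))
  cat("mean frequencies:\n")
  print(round(x$mean_freqs, 4))
  invisible(x)
}

#' Built-in character-state groupings
#'
#' Standard recodings used when assessing grouped compositional bias:
#' purines/pyrimidines (RY) and AT/GC for nucleotides, and a hydrophobic
#' amino-acid class (A, W, M, I, L, F, P) for proteins. Further classes
#' (polar, charged, ...) are deliberately left to user-supplied definitions.
#'
#' @param alphabet an `rcfv_alphabet`.
#' @return Named list of character vectors of member states.
#' @export
state_group_presets <- function(alphabet) {
  switch(alphabet$name,
    dna = list(purines = c("A", "G"), pyrimidines = c("C", "T"),
               AT = c("A", "T"), GC = c("G", "C")),
    protein = list(hydrophobic = c("A", "W", "M", "I", "L", "F", "P")),
    list())
}

#' Collapse character states into groups
#'
#' Sums counts and frequencies of member states into group pseudo-states
#' (e.g. purine frequency = freq(A) + freq(G)). Frequencies always remain
#' fractions of each taxon's effective length, so when the groups partition
#' the full alphabet they sum to 1 per taxon, and when they cover a subset
#' they are that subset's share of the sequence. Group frequencies are
#' computed as exact sums of member-state frequencies (mass conservation).
#'
#' @param ft an `rcfv_freqtab`.
#' @param groups named list of disjoint, non-empty character vectors of
#'   alphabet states.
#' @return An `rcfv_freqtab` over the group pseudo-alphabet. Its
#'   `alphabet$n_states` is the number of groups (the `c` used when
#'   normalizing metrics on recoded data).
#' @export
collapse_states <- function(ft, groups) {
  if (length(groups) == 0L || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    stop("groups must be a non-empty named list")
  members <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(members, ft$alphabet$states)
  if (length(unknown) > 0L)
    stop(sprintf("unknown state '%s' in group definition", unknown[1L]))
  if (anyDuplicated(members))
    stop(sprintf("state '%s' appears in more than one group",
                 members[duplicated(members)][1L]))
  if (any(lengths(groups) == 0L)) stop("groups must be non-empty")

  gnames <- names(groups)
  counts <- sapply(groups, function(g)
    rowSums(ft$counts[, g, drop = FALSE]))
  freqs <- sapply(groups, function(g)
    rowSums(ft$freqs[, g, drop = FALSE]))
  counts <- matrix(counts, nrow = ft$n_taxa,
                   dimnames = list(rownames(ft$counts), gnames))
  freqs <- matrix(freqs, nrow = ft$n_taxa,
                  dimnames = list(rownames(ft$freqs), gnames))
  grp_alphabet <- structure(
    list(name = paste0(ft$alphabet$name, ":grouped"),
         states = gnames, n_states = length(gnames),
         missing_codes = ft$alphabet$missing_codes,
         canonical_map = NULL),
    class = "rcfv_alphabet")
  structure(
    list(counts = counts, freqs = freqs,
         mean_freqs = colMeans(freqs),
         effective_lengths = ft$effective_lengths,
         n_taxa = ft$n_taxa, n_columns = ft$n_columns,
         alphabet = grp_alphabet),
    class = "rcfv_freqtab")
}
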