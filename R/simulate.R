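# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed for replicate k of a study seeded with `seed`
# (documented splitting scheme: base seed + replicate index, kept in 32-bit
# integer range).
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) + as.double(k)) %% 2147483647)
}

#' Configuration for homogeneous alignment simulation
#'
#' The simulator draws every cell i.i.d. from a single stationary state
#' distribution, so the generated alignments are compositionally homogeneous
#' by construction: every taxon has the same expected composition, and any
#' non-zero RCFV observed on them is pure sampling noise. This is the
#' cleanest possible background against which to measure how alignment
#' dimensions bias a heterogeneity metric.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param n_columns number of alignment columns (>= 1).
#' @param alphabet an `rcfv_alphabet` (default DNA).
#' @param state_frequencies probability vector over the alphabet's states
#'   (default uniform); must be non-negative and sum to 1.
#' @param seed integer RNG seed.
#' @param replicates number of replicates for study-level functions (>= 1).
#' @return An object of class `rcfv_sim_config`.
#' @export
simulation_config <- function(n_taxa, n_columns, alphabet = dna_alphabet(),
                              state_frequencies = NULL, seed = 1L,
                              replicates = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  if (n_columns < 1L) stop("n_columns must be at least 1")
  if (replicates < 1L) stop("replicates must be at least 1")
  if (is.null(state_frequencies))
    state_frequencies <- rep(1 / alphabet$n_states, alphabet$n_states)
  if (length(state_frequencies) != alphabet$n_states)
    stop("state_frequencies must have one entry per alphabet state")
  if (any(state_frequencies < 0))
    stop("state_frequencies must be non-negative")
  if (abs(sum(state_frequencies) - 1) > 1e-12)
    stop("state_frequencies must sum to 1")
  if (any(state_frequencies == 1))
    warning("degenerate state_frequencies: one state has probability 1; RCFV will be 0")
  structure(
    list(n_taxa = as.integer(n_taxa), n_columns = as.integer(n_columns),
         alphabet = alphabet,
         state_frequencies = stats::setNames(state_frequencies,
                                             alphabet$states),
         seed = as.integer(seed), replicates = as.integer(replicates)),
    class = "rcfv_sim_config")
}

#' Simulate a compositionally homogeneous alignment
#'
#' Every cell is drawn i.i.d. from `cfg$state_frequencies` with the seeded
#' generator; the same config always yields the same alignment.
#'
#' @param cfg an `rcfv_sim_config`.
#' @return An `rcfv_alignment` with taxa labelled `t1 ... tn`.
#' @export
simulate_homogeneous <- function(cfg) {
  stopifnot(inherits(cfg, "rcfv_sim_config"))
  .with_seed(cfg$seed, {
    mat <- matrix(sample(cfg$alphabet$states, cfg$n_taxa * cfg$n_columns,
                         replace = TRUE, prob = cfg$state_frequencies),
                  nrow = cfg$n_taxa, ncol = cfg$n_columns,
                  dimnames = list(paste0("t", seq_len(cfg$n_taxa)), NULL))
    new_alignment(mat, cfg$alphabet)
  })
}

#' Grid study of metric dependence on alignment dimensions
#'
#' Simulates homogeneous alignments over the cross of the given taxon counts
#' and column counts, scores each replicate with raw RCFV and nRCFV, and
#' regresses the per-cell mean of each metric on `p` and on `n`. On
#' homogeneous data the raw RCFV mean falls as columns are added (its
#' sampling noise shrinks like \eqn{p^{-1/2}}) while the normalized metric
#' stays flat — the motivating size bias and its correction.
#'
#' @param taxa integer vector of taxon counts (>= 2 distinct values).
#' @param positions integer vector of column counts (>= 2 distinct values).
#' @param alphabet an `rcfv_alphabet` (default DNA).
#' @param state_frequencies stationary distribution (default uniform).
#' @param replicates replicates per grid cell (>= 2).
#' @param seed integer seed; replicate r of cell k runs on substream seed
#'   `seed + (k-1)*replicates + r`.
#' @return An object of class `rcfv_bias_study`: list with `replicates`
#'   (one row per simulated alignment: n, p, replicate, rcfv, nrcfv),
#'   `summary` (per-cell means and standard deviations), and `trends`
#'   (regression slope, standard error and p-value of each cell-mean metric
#'   against p and against n).
#' @export
run_bias_study <- function(taxa, positions, alphabet = dna_alphabet(),
                           state_frequencies = NULL, replicates = 100L,
                           seed = 1L) {
  taxa <- sort(unique(as.integer(taxa)))
  positions <- sort(unique(as.integer(positions)))
  if (length(taxa) < 2L || length(positions) < 2L)
    stop("the grid needs at least 2 distinct taxon counts and 2 distinct column counts")
  if (replicates < 2L) stop("at least 2 replicates per cell are required")

  grid <- expand.grid(n = taxa, p = positions, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid) * replicates)
  idx <- 0L
  for (k in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      cfg <- simulation_config(grid$n[k], grid$p[k], alphabet,
                               state_frequencies,
                               seed = .sub_seed(seed, (k - 1L) * replicates + r))
      ft <- tabulate_frequencies(simulate_homogeneous(cfg))
      raw <- rcfv_total(ft)
      rows[[idx]] <- data.frame(
        n = grid$n[k], p = grid$p[k], replicate = r, rcfv = raw,
        nrcfv = nrcfv(raw, grid$p[k], grid$n[k], alphabet$n_states))
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, list(reps$n, reps$p)), function(d)
    data.frame(n = d$n[1L], p = d$p[1L],
               mean_rcfv = mean(d$rcfv), sd_rcfv = stats::sd(d$rcfv),
               mean_nrcfv = mean(d$nrcfv), sd_nrcfv = stats::sd(d$nrcfv))))
  summ <- summ[order(summ$n, summ$p), ]
  rownames(summ) <- NULL

  trend <- function(metric, var) {
    fit <- stats::lm(summ[[metric]] ~ summ[[var]])
    cf <- summary(fit)$coefficients
    data.frame(metric = metric, against = var,
               slope = cf[2L, 1L], se = cf[2L, 2L], p_value = cf[2L, 4L])
  }
  trends <- rbind(trend("mean_rcfv", "p"), trend("mean_rcfv", "n"),
                  trend("mean_nrcfv", "p"), trend("mean_nrcfv", "n"))
  rownames(trends) <- NULL
  structure(list(replicates = reps, summary = summ, trends = trends,
                 seed = as.integer(seed)),
            class = "rcfv_bias_study")
}

#' @export
print.rcfv_bias_study <- function(x, ...) {
  cat(sprintf("<bias study: %d grid cells x %d replicates>\n",
              nrow(x$summary), max(x$replicates$replicate)))
  print(x$summary, digits = 4)
  cat("trends of cell means:\n")
  print(x$trends, digits = 4)
  invisible(x)
}

#' Inject missing data uniformly at random
#'
#' Sets exactly `round(fraction * n * p)` uniformly chosen cells to missing,
#' resampling the mask if it would leave any taxon without a single
#' non-missing cell.
#'
#' @param aln an `rcfv_alignment`.
#' @param fraction fraction of cells to blank, in `[0, 1)`.
#' @param seed integer seed.
#' @return An `rcfv_alignment` with the same dimensions and alphabet.
#' @export
apply_missingness <- function(aln, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- nrow(aln); p <- ncol(aln)
  k <- round(fraction * n * p)
  if (k == 0L) return(aln)
  if (k > n * (p - 1L))
    stop("fraction would unavoidably leave a taxon with no data")
  .with_seed(seed, {
    for (try in seq_len(1000L)) {
      cells <- sample.int(n * p, k)
      blanked <- tabulate(((cells - 1L) %% n) + 1L, nbins = n)
      if (all(blanked < p)) {
        mat <- unclass(aln)
        mat[cells] <- NA_character_
        return(new_alignment(mat, alignment_alphabet(aln)))
      }
    }
    stop("could not draw a missingness mask keeping every taxon sampled")
  })
}

#' Simulate a gapped/ungapped mimic pair of a template alignment
#'
#' Emulates a template's composition and missing-data structure: both
#' replicates draw cells i.i.d. from the template's per-taxon composition
#' (estimated from that taxon's non-missing cells), the gapped replicate
#' copies the template's missing mask verbatim, and the ungapped replicate
#' fills every cell. Per-taxon (rather than pooled) composition is used so
#' the two replicates differ only by the mask, not by composition shifts.
#' Comparing the metrics of the pair isolates the effect of missing data
#' itself on the metric.
#'
#' @param template an `rcfv_alignment` (its missing cells define the mask).
#' @param seed integer seed.
#' @return An object of class `rcfv_mimic_pair`: list with `gapped` and
#'   `ungapped` alignments and a `template_summary` (per-taxon frequencies
#'   and missing fractions, overall missing fraction).
#' @export
mimic_pair <- function(template, seed = 1L) {
  ft <- tabulate_frequencies(template)
  n <- nrow(template); p <- ncol(template)
  states <- alignment_alphabet(template)$states
  draw_rows <- function() {
    mat <- matrix(NA_character_, n, p, dimnames = list(rownames(template), NULL))
    for (i in seq_len(n))
      mat[i, ] <- sample(states, p, replace = TRUE, prob = ft$freqs[i, ])
    mat
  }
  .with_seed(seed, {
    gapped <- draw_rows()
    gapped[is.na(unclass(template))] <- NA_character_
    ungapped <- draw_rows()
    list_summary <- list(
      per_taxon_freqs = ft$freqs,
      per_taxon_missing = 1 - ft$effective_lengths / p,
      missing_fraction = mean(is.na(unclass(template))))
    structure(
      list(gapped = new_alignment(gapped, alignment_alphabet(template)),
           ungapped = new_alignment(ungapped, alignment_alphabet(template)),
           template_summary = list_summary),
      class = "rcfv_mimic_pair")
  })
}

#' Missing-data study over mimic pairs
#'
#' Builds templates at the requested missing-data fractions from one
#' homogeneous base alignment, simulates seeded mimic pairs for each, and
#' records the relative RCFV difference of each pair,
#' `(RCFV_gapped - RCFV_ungapped) / RCFV_gapped`. A linear regression of
#' the per-pair relative difference on the missing fraction summarizes
#' whether the gapped/ungapped gap trends with the amount of missing data.
#'
#' @param base an `rcfv_alignment` with no missing cells (the common
#'   template source).
#' @param fractions numeric vector of missing-data fractions in `[0, 1)`.
#' @param pairs total number of mimic pairs, spread as evenly as possible
#'   across the fractions.
#' @param seed integer seed.
#' @return An object of class `rcfv_missing_study`: list with `pairs` (one
#'   row per pair: fraction, rcfv_gapped, rcfv_ungapped, rel_diff),
#'   `by_fraction` (mean and sd of rel_diff per fraction) and `trend`
#'   (slope, standard error, 95% confidence interval and p-value of
#'   rel_diff against fraction).
#' @export
run_missingness_study <- function(base, fractions, pairs = 100L, seed = 1L) {
  if (any(is.na(unclass(base))))
    stop("the base alignment must be complete (no missing cells)")
  if (length(fractions) < 2L) stop("at least 2 missing fractions are needed")
  n_frac <- length(fractions)
  per <- diff(round(seq(0, pairs, length.out = n_frac + 1L)))
  rows <- vector("list", pairs)
  idx <- 0L
  for (f in seq_len(n_frac)) {
    template <- apply_missingness(base, fractions[f], seed = .sub_seed(seed, f))
    for (r in seq_len(per[f])) {
      idx <- idx + 1L
      pair <- mimic_pair(template, seed = .sub_seed(seed, 1000L * f + r))
      rg <- rcfv_total(tabulate_frequencies(pair$gapped))
      ru <- rcfv_total(tabulate_frequencies(pair$ungapped))
      rows[[idx]] <- data.frame(fraction = fractions[f], pair = r,
                                rcfv_gapped = rg, rcfv_ungapped = ru,
                                rel_diff = (rg - ru) / rg)
    }
  }
  d <- do.call(rbind, rows)
  by_frac <- do.call(rbind, lapply(split(d, d$fraction), function(s)
    data.frame(fraction = s$fraction[1L], mean_rel_diff = mean(s$rel_diff),
               sd_rel_diff = stats::sd(s$rel_diff), n_pairs = nrow(s))))
  rownames(by_frac) <- NULL
  fit <- stats::lm(rel_diff ~ fraction, data = d)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)["fraction", ]
  trend <- data.frame(slope = cf["fraction", 1L], se = cf["fraction", 2L],
                      ci_lower = ci[[1L]], ci_upper = ci[[2L]],
                      p_value = cf["fraction", 4L])
  structure(list(pairs = d, by_fraction = by_frac, trend = trend,
                 seed = as.integer(seed)),
            class = "rcfv_missing_study")
}

#' @export
print.rcfv_missing_study <- function(x, ...) {
  cat(sprintf("<missing-data study: %d mimic pairs over fractions %s>\n",
              nrow(x$pairs),
              paste(unique(x$pairs$fraction), collapse = ", ")))
  print(x$by_fraction, digits = 4)
  cat(sprintf("trend of rel_diff on fraction: slope %.4g (95%% CI %.4g .. %.4g)\n",
              x$trend$slope, x$trend$ci_lower, x$trend$ci_upper))
  invisible(x)
}
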