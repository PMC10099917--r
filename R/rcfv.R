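#' Relative Composition Frequency Variability (RCFV)
#'
#' RCFV quantifies compositional heterogeneity of an alignment as the mean
#' absolute deviation of per-taxon state frequencies from the dataset-mean
#' frequencies, summed over all taxa and states:
#' \deqn{RCFV = \sum_{i=1}^{n} \sum_{j=1}^{m} |\mu_{ij} - \bar\mu_j| / n.}
#' Restricting the sum to one state \eqn{j} gives the character-specific
#' component (csRCFV); restricting it to one taxon \eqn{i} gives the
#' taxon-specific component (tsRCFV). The components are exact additive
#' decompositions of the total: \eqn{RCFV = \sum_j csRCFV_j = \sum_i
#' tsRCFV_i}, so the share of the total attributable to one state or taxon
#' is a simple ratio.
#'
#' @param ft an `rcfv_freqtab` (possibly collapsed with [collapse_states()]).
#' @return `rcfv_total()`: a single non-negative number; it is zero exactly
#'   when every taxon's frequency vector equals the mean vector.
#' @export
rcfv_total <- function(ft) {
  sum(.rcfv_dev(ft)) / ft$n_taxa
}

.rcfv_dev <- function(ft) {
  abs(sweep(ft$freqs, 2L, ft$mean_freqs))
}

#' @rdname rcfv_total
#' @param state canonical state (or group name of a collapsed table); if
#'   `NULL`, the named vector over all states is returned.
#' @return `cs_rcfv()`: csRCFV of one state, or the named vector of all
#'   per-state values.
#' @export
cs_rcfv <- function(ft, state = NULL) {
  v <- colSums(.rcfv_dev(ft)) / ft$n_taxa
  if (is.null(state)) return(v)
  if (!state %in% names(v)) stop(sprintf("unknown state '%s'", state))
  v[[state]]
}

#' @rdname rcfv_total
#' @param taxon taxon label; if `NULL`, the named vector over all taxa is
#'   returned.
#' @return `ts_rcfv()`: tsRCFV of one taxon, or the named vector of all
#'   per-taxon values.
#' @export
ts_rcfv <- function(ft, taxon = NULL) {
  v <- rowSums(.rcfv_dev(ft)) / ft$n_taxa
  if (is.null(taxon)) return(v)
  if (!taxon %in% names(v)) stop(sprintf("unknown taxon '%s'", taxon))
  v[[taxon]]
}

#' Full RCFV metric set for an alignment
#'
#' Computes the total RCFV, all character-specific and taxon-specific
#' components, and (optionally) components for grouped states such as
#' purines/pyrimidines. Use [normalize_all()] to populate the
#' size-normalized counterparts.
#'
#' @param x an `rcfv_alignment` or `rcfv_freqtab`.
#' @param groups optional named list of state groups (see
#'   [state_group_presets()]); each group's csRCFV is computed on the
#'   collapsed table.
#' @return An object of class `rcfv_result`: a list with `rcfv`, `cs_rcfv`
#'   (named vector), `ts_rcfv` (named vector), `group_cs_rcfv` (named vector
#'   or `NULL`), `n_taxa`, `n_columns`, `n_states`, and normalized slots
#'   (`nrcfv`, `ncs_rcfv`, `nts_rcfv`, `group_ncs_rcfv`) that are `NULL`
#'   until [normalize_all()] is applied.
#' @export
rcfv_metrics <- function(x, groups = NULL) {
  ft <- if (inherits(x, "rcfv_freqtab")) x else tabulate_frequencies(x)
  group_cs <- NULL
  if (!is.null(groups)) {
    # each group is collapsed on its own, so alternative (overlapping)
    # groupings like purines and AT can be reported side by side
    group_cs <- vapply(names(groups), function(g)
      cs_rcfv(collapse_states(ft, groups[g]), g), numeric(1L))
  }
  structure(
    list(rcfv = rcfv_total(ft),
         cs_rcfv = cs_rcfv(ft),
         ts_rcfv = ts_rcfv(ft),
         group_cs_rcfv = group_cs,
         n_taxa = ft$n_taxa, n_columns = ft$n_columns,
         n_states = ft$alphabet$n_states,
         nrcfv = NULL, ncs_rcfv = NULL, nts_rcfv = NULL,
         group_ncs_rcfv = NULL),
    class = "rcfv_result")
}

#' @export
print.rcfv_result <- function(x, ...) {
  cat(sprintf("<RCFV metrics: n = %d taxa, p = %d columns, c = %d states>\n",
              x$n_taxa, x$n_columns, x$n_states))
  cat(sprintf("  RCFV  = %.6g\n", x$rcfv))
  if (!is.null(x$nrcfv)) cat(sprintf("  nRCFV = %.6g\n", x$nrcfv))
  cat(sprintf("  csRCFV range: [%.6g, %.6g]; tsRCFV range: [%.6g, %.6g]\n",
              min(x$cs_rcfv), max(x$cs_rcfv),
              min(x$ts_rcfv), max(x$ts_rcfv)))
  invisible(x)
}

#' Percentage contribution of components to the total RCFV
#'
#' Because the raw components decompose the total additively, the share of
#' heterogeneity carried by a state or taxon is `100 * component / total`
#' (e.g. with RCFV 0.1 and csRCFV(A) 0.025, state A contributes 25%). The
#' normalized metrics are not additive, so no analogous shares exist for
#' them.
#'
#' @param total total RCFV, or an `rcfv_result`.
#' @param component a csRCFV or tsRCFV value (ignored when `total` is an
#'   `rcfv_result`).
#' @return A percentage in `[0, 100]`, or, for an `rcfv_result`, a list with
#'   per-state and per-taxon percentage vectors.
#' @export
rcfv_contribution <- function(total, component = NULL) {
  if (inherits(total, "rcfv_result")) {
    return(list(states = 100 * total$cs_rcfv / total$rcfv,
                taxa = 100 * total$ts_rcfv / total$rcfv))
  }
  if (is.null(component)) stop("a component value is required")
  if (total <= 0) stop("total RCFV must be positive to compute shares")
  100 * component / total
}

#' Predicted frequency shifts from a single substitution
#'
#' For a complete-data alignment with `n` taxa and `p` columns, changing one
#' cell from state a to state g in one taxon shifts that taxon's
#' \eqn{\mu_a} by \eqn{+1/p} and \eqn{\mu_g} by \eqn{-1/p}, and the dataset
#' means \eqn{\bar\mu_a, \bar\mu_g} by \eqn{\pm 1/(np)}. The affected
#' taxon's deviation terms therefore move by \eqn{(n-1)/(np)} while every
#' unaffected taxon's move by \eqn{1/(np)}. Both factors shrink as `p`
#' grows; as `n` grows the affected-taxon factor approaches `1/p` from
#' below. This is the analytic footprint of the size bias that the
#' normalized metrics correct. States not involved in the change are
#' untouched entirely.
#'
#' @param n number of taxa (>= 2).
#' @param p number of columns (>= 1).
#' @return An object of class `rcfv_perturbation`: list with
#'   `affected_shift` = (n-1)/(n p), `background_shift` = 1/(n p), `n_taxa`,
#'   `n_columns`.
#' @export
predict_single_change <- function(n, p) {
  if (n < 2L) stop("n must be at least 2")
  if (p < 1L) stop("p must be at least 1")
  structure(
    list(affected_shift = (n - 1) / (n * p),
         background_shift = 1 / (n * p),
         n_taxa = n, n_columns = p),
    class = "rcfv_perturbation")
}

#' @export
print.rcfv_perturbation <- function(x, ...) {
  cat(sprintf(
    "<single-change shifts (n = %d, p = %d): affected (n-1)/(np) = %.6g, background 1/(np) = %.6g>\n",
    x$n_taxa, x$n_columns, x$affected_shift, x$background_shift))
  invisible(x)
}
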