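#' Size-normalized RCFV metrics
#'
#' The raw RCFV metrics depend on alignment size: sampling noise in the
#' per-taxon frequencies shrinks as sequences lengthen, so raw values fall
#' with the number of positions `p` and are modulated by the number of taxa
#' `n` and character states `c`. The normalized family divides each raw
#' metric by a size-dependent constant so that values are comparable across
#' alignments of different dimensions:
#' \deqn{nRCFV = RCFV / (p^{-0.5}\, n^{0.01}\, c \cdot 100)}
#' \deqn{ntsRCFV = tsRCFV / (p^{-0.5}\, n^{-1}\, c \cdot 100)}
#' \deqn{ncsRCFV = csRCFV / (p^{-0.5} \cdot 100)}
#' The exponents are fixed published constants, not refit by this package.
#' `c` is the nominal state count of the alphabet in use (4 for
#' nucleotides, 20 for amino acids, the group count for recoded data such
#' as RY) — never the number of states observed. The csRCFV normalization is
#' deliberately independent of `n` and `c` and applies unchanged to single
#' states and to grouped states. Note that unlike the raw metrics the
#' normalized metrics are not additive: nRCFV is not the sum of the
#' ncsRCFV or ntsRCFV values.
#'
#' @param rcfv,tsrcfv,csrcfv raw metric value(s) (vectors are normalized
#'   elementwise).
#' @param p number of alignment columns (>= 1), including columns missing in
#'   some taxa.
#' @param n number of taxa (>= 2).
#' @param c number of possible character states (>= 2).
#' @return The normalized value(s).
#' @export
nrcfv <- function(rcfv, p, n, c) {
  .check_npc(p, n, c)
  if (any(rcfv < 0)) stop("rcfv must be non-negative")
  rcfv / (p^-0.5 * n^0.01 * c * 100)
}

#' @rdname nrcfv
#' @export
nts_rcfv <- function(tsrcfv, p, n, c) {
  .check_npc(p, n, c)
  if (any(tsrcfv < 0)) stop("tsrcfv must be non-negative")
  tsrcfv / (p^-0.5 * n^-1 * c * 100)
}

#' @rdname nrcfv
#' @export
ncs_rcfv <- function(csrcfv, p) {
  if (p < 1) stop("p must be at least 1")
  if (any(csrcfv < 0)) stop("csrcfv must be non-negative")
  csrcfv / (p^-0.5 * 100)
}

.check_npc <- function(p, n, c) {
  if (p < 1) stop("p must be at least 1")
  if (n < 2) stop("n must be at least 2")
  if (c < 2) stop("c must be at least 2")
}

#' Populate the normalized metrics of an `rcfv_result`
#'
#' Applies the normalization constants to the total, per-taxon and per-state
#' (including grouped-state) metrics stored in the result, using the
#' result's own `n`, `p` and `c`. Raw fields are untouched; applying twice
#' equals applying once.
#'
#' @param mr an `rcfv_result` from [rcfv_metrics()].
#' @return The same `rcfv_result` with `nrcfv`, `nts_rcfv`, `ncs_rcfv` (and
#'   `group_ncs_rcfv` when group metrics are present) filled in.
#' @export
normalize_all <- function(mr) {
  if (!inherits(mr, "rcfv_result")) stop("expected an 'rcfv_result'")
  mr$nrcfv <- nrcfv(mr$rcfv, mr$n_columns, mr$n_taxa, mr$n_states)
  mr$nts_rcfv <- nts_rcfv(mr$ts_rcfv, mr$n_columns, mr$n_taxa, mr$n_states)
  mr$ncs_rcfv <- ncs_rcfv(mr$cs_rcfv, mr$n_columns)
  if (!is.null(mr$group_cs_rcfv))
    mr$group_ncs_rcfv <- ncs_rcfv(mr$group_cs_rcfv, mr$n_columns)
  mr
}
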