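# Full-precision numeric formatting for machine-readable TSVs
# (round-trips through as.numeric).
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a metric report bundle
#'
#' Writes `summary.tsv` (dataset-level metrics), `taxa.tsv` (per-taxon
#' tsRCFV/ntsRCFV), `states.tsv` (per-state and grouped-state
#' csRCFV/ncsRCFV) and `report.json` (a JSON mirror of all three plus a
#' provenance block) into a directory. Every number in the bundle equals
#' the corresponding library-call result bit-for-bit; numbers are written
#' in full double precision.
#'
#' @param mr an `rcfv_result`; normalized slots are populated with
#'   [normalize_all()] if absent.
#' @param dir output directory (created if needed).
#' @param input input file path recorded in provenance.
#' @param alphabet the `rcfv_alphabet` used (for provenance).
#' @param seed seed to echo in provenance, if any randomness was involved.
#' @return Invisibly, the list of file paths written.
#' @export
write_report_bundle <- function(mr, dir, input = NA_character_,
                                alphabet = NULL, seed = NULL) {
  if (is.null(mr$nrcfv)) mr <- normalize_all(mr)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  summary_df <- data.frame(n_taxa = mr$n_taxa, n_columns = mr$n_columns,
                           n_states = mr$n_states,
                           rcfv = mr$rcfv, nrcfv = mr$nrcfv)
  taxa_df <- data.frame(taxon = names(mr$ts_rcfv),
                        tsrcfv = unname(mr$ts_rcfv),
                        ntsrcfv = unname(mr$nts_rcfv))
  states_df <- data.frame(state = names(mr$cs_rcfv),
                          kind = "state",
                          csrcfv = unname(mr$cs_rcfv),
                          ncsrcfv = unname(mr$ncs_rcfv))
  if (!is.null(mr$group_cs_rcfv))
    states_df <- rbind(states_df, data.frame(
      state = names(mr$group_cs_rcfv), kind = "group",
      csrcfv = unname(mr$group_cs_rcfv),
      ncsrcfv = unname(mr$group_ncs_rcfv)))

  provenance <- list(
    input = input,
    alphabet = if (is.null(alphabet)) NA_character_ else alphabet$name,
    missing_codes = if (is.null(alphabet)) character()
                    else alphabet$missing_codes,
    tool = "nrcfv",
    version = as.character(utils::packageVersion("nrcfv")),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed))

  paths <- list(summary = file.path(dir, "summary.tsv"),
                taxa = file.path(dir, "taxa.tsv"),
                states = file.path(dir, "states.tsv"),
                json = file.path(dir, "report.json"))
  .write_tsv(summary_df, paths$summary)
  .write_tsv(taxa_df, paths$taxa)
  .write_tsv(states_df, paths$states)
  jsonlite::write_json(
    list(summary = summary_df, taxa = taxa_df, states = states_df,
         provenance = provenance),
    paths$json, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(paths)
}

#' Write bias-study tables
#'
#' Writes `replicates.tsv` (one row per simulated alignment) and
#' `summary.tsv` (one row per grid cell, plus the trend table as
#' `trends.tsv`).
#'
#' @param study an `rcfv_bias_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_bias_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(replicates = file.path(dir, "replicates.tsv"),
                summary = file.path(dir, "summary.tsv"),
                trends = file.path(dir, "trends.tsv"))
  .write_tsv(study$replicates, paths$replicates)
  .write_tsv(study$summary, paths$summary)
  .write_tsv(study$trends, paths$trends)
  invisible(paths)
}

#' Write partition-analysis tables
#'
#' Writes the per-gene metric table (`genes.tsv`), the quantile assignments
#' under both metrics (`assignment_rcfv.tsv`, `assignment_nrcfv.tsv`) and
#' the selection comparison (`comparison.tsv`, `crosstab.tsv`).
#'
#' @param tbl an `rcfv_gene_table`.
#' @param qa,qb the two `rcfv_quantiles` being compared (by convention `qa`
#'   from raw RCFV, `qb` from nRCFV).
#' @param cmp the `rcfv_selection_comparison` of `qa` vs `qb`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_partition_report <- function(tbl, qa, qb, cmp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genes = file.path(dir, "genes.tsv"),
                assignment_a = file.path(dir, sprintf("assignment_%s.tsv", qa$metric)),
                assignment_b = file.path(dir, sprintf("assignment_%s.tsv", qb$metric)),
                comparison = file.path(dir, "comparison.tsv"),
                crosstab = file.path(dir, "crosstab.tsv"))
  .write_tsv(as.data.frame(tbl), paths$genes)
  .write_tsv(qa$assignment, paths$assignment_a)
  .write_tsv(qb$assignment, paths$assignment_b)
  .write_tsv(cmp$per_bin, paths$comparison)
  ct <- as.data.frame(cmp$crosstab)
  ct <- cbind(data.frame(b_bin = rownames(cmp$crosstab)), ct)
  .write_tsv(ct, paths$crosstab)
  invisible(paths)
}
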