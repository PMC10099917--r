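#' Score gene partitions independently
#'
#' Each gene alignment is scored with its own dimensions: `n` counts only
#' the taxa having at least one non-missing cell in that gene (a taxon with
#' no data carries no compositional information for it), `p` is the gene's
#' column count, and `c` the alphabet's state count. Both raw RCFV and
#' nRCFV are reported so selections based on either metric can be compared.
#'
#' @param genes named list of `rcfv_alignment` objects.
#' @return A `data.frame` of class `rcfv_gene_table` with columns `gene`,
#'   `n_taxa`, `p`, `c`, `rcfv`, `nrcfv`.
#' @export
score_partitions <- function(genes) {
  if (length(genes) == 0L) stop("no gene alignments supplied")
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("genes must be a named list")
  if (anyDuplicated(names(genes)))
    stop("gene names must be unique")
  rows <- lapply(names(genes), function(g) {
    aln <- genes[[g]]
    present <- rowSums(!is.na(unclass(aln))) > 0L
    if (sum(present) < 2L)
      stop(sprintf("gene '%s' has fewer than 2 sampled taxa", g))
    sub <- new_alignment(unclass(aln)[present, , drop = FALSE],
                         alignment_alphabet(aln))
    ft <- tabulate_frequencies(sub)
    raw <- rcfv_total(ft)
    data.frame(gene = g, n_taxa = ft$n_taxa, p = ft$n_columns,
               c = ft$alphabet$n_states, rcfv = raw,
               nrcfv = nrcfv(raw, ft$n_columns, ft$n_taxa,
                             ft$alphabet$n_states))
  })
  tbl <- do.call(rbind, rows)
  class(tbl) <- c("rcfv_gene_table", "data.frame")
  tbl
}

#' Assign genes to quantile bins by a heterogeneity metric
#'
#' Sorts genes ascending by the chosen metric (bin 1 = least heterogeneous),
#' breaking ties lexicographically by gene name, and splits them into `k`
#' bins as equal in size as possible, allocating the remainder one extra
#' gene to the earliest bins. The default `k = 6` gives sextiles, the
#' binning used when curating supermatrices by compositional heterogeneity.
#'
#' @param tbl an `rcfv_gene_table` from [score_partitions()].
#' @param metric `"nrcfv"` or `"rcfv"`.
#' @param k number of bins (default 6).
#' @return An object of class `rcfv_quantiles`: list with `assignment`
#'   (data.frame gene, value, bin), `bin_sizes`, `metric`, `k`.
#' @export
assign_quantiles <- function(tbl, metric = c("nrcfv", "rcfv"), k = 6L) {
  metric <- match.arg(metric)
  g <- nrow(tbl)
  if (k < 1L || k > g)
    stop(sprintf("k must be between 1 and the number of genes (%d)", g))
  ord <- order(tbl[[metric]], tbl$gene)
  sizes <- rep(g %/% k, k) + (seq_len(k) <= g %% k)
  assignment <- data.frame(
    gene = tbl$gene[ord],
    value = tbl[[metric]][ord],
    bin = rep(seq_len(k), times = sizes))
  structure(list(assignment = assignment, bin_sizes = sizes,
                 metric = metric, k = k),
            class = "rcfv_quantiles")
}

#' @export
print.rcfv_quantiles <- function(x, ...) {
  cat(sprintf("<%d-quantile assignment of %d genes by %s; bin sizes: %s>\n",
              x$k, nrow(x$assignment), x$metric,
              paste(x$bin_sizes, collapse = ", ")))
  invisible(x)
}

.bin_members <- function(q) split(q$assignment$gene, q$assignment$bin)

#' Compare gene selections between two quantile assignments
#'
#' For each bin, reports the percentage of genes in assignment `b`'s bin
#' that are absent from assignment `a`'s same bin, the summed alignment
#' length of the bin under each assignment, and a cross-tabulation of which
#' `a`-bin the non-shared genes of each `b`-bin fall into. This is the
#' comparison used to quantify how strongly two metrics disagree about
#' which genes belong to which heterogeneity stratum.
#'
#' @param a,b `rcfv_quantiles` over the same gene set with equal `k`.
#' @param tbl the `rcfv_gene_table` the assignments were made from (supplies
#'   gene lengths).
#' @return An object of class `rcfv_selection_comparison`: list with
#'   `per_bin` (bin, pct_nonshared, pct_nonshared_rounded, length_a,
#'   length_b) and `crosstab` (k x k matrix; row = b-bin, column =
#'   destination a-bin of its non-shared genes).
#' @export
compare_selections <- function(a, b, tbl) {
  if (a$k != b$k) stop("assignments must use the same number of bins")
  if (!setequal(a$assignment$gene, b$assignment$gene) ||
      !setequal(a$assignment$gene, tbl$gene))
    stop("assignments and gene table must cover the same genes")
  k <- a$k
  bins_a <- .bin_members(a); bins_b <- .bin_members(b)
  lens <- stats::setNames(tbl$p, tbl$gene)
  a_bin_of <- stats::setNames(a$assignment$bin, a$assignment$gene)
  crosstab <- matrix(0L, k, k, dimnames = list(b_bin = seq_len(k),
                                               a_bin = seq_len(k)))
  per_bin <- lapply(seq_len(k), function(i) {
    nonshared <- setdiff(bins_b[[i]], bins_a[[i]])
    for (g in nonshared)
      crosstab[i, a_bin_of[[g]]] <<- crosstab[i, a_bin_of[[g]]] + 1L
    pct <- 100 * length(nonshared) / length(bins_b[[i]])
    data.frame(bin = i, pct_nonshared = pct,
               pct_nonshared_rounded = round(pct),
               length_a = sum(lens[bins_a[[i]]]),
               length_b = sum(lens[bins_b[[i]]]))
  })
  structure(list(per_bin = do.call(rbind, per_bin), crosstab = crosstab),
            class = "rcfv_selection_comparison")
}

#' @export
print.rcfv_selection_comparison <- function(x, ...) {
  cat("<selection comparison>\n")
  print(x$per_bin, digits = 4)
  invisible(x)
}

#' Concatenate the genes of bins 1..upto into a supermatrix
#'
#' Column-wise concatenation over the union of taxa of the member genes,
#' padding taxa absent from a gene with missing cells. Genes are
#' concatenated in assignment (bin, then metric) order; taxa are sorted for
#' determinism. A 1-based inclusive per-gene boundary table is attached as
#' the `"boundaries"` attribute.
#'
#' @param assignment an `rcfv_quantiles`.
#' @param genes the named list of gene alignments the assignment covers.
#' @param upto last bin to include (cumulative datasets bin 1 through
#'   `upto`).
#' @return An `rcfv_alignment` supermatrix.
#' @export
cumulative_dataset <- function(assignment, genes, upto) {
  if (upto < 1L || upto > assignment$k) stop("upto must be in 1..k")
  sel <- assignment$assignment[assignment$assignment$bin <= upto, ]
  member <- sel$gene
  if (length(member) == 0L) stop("no genes in the requested bins")
  missing_genes <- setdiff(member, names(genes))
  if (length(missing_genes) > 0L)
    stop(sprintf("gene '%s' not found in the supplied gene list",
                 missing_genes[1L]))
  alns <- genes[member]
  alpha <- alignment_alphabet(alns[[1L]])
  if (!all(vapply(alns, function(a)
    identical(alignment_alphabet(a)$states, alpha$states), logical(1L))))
    stop("all genes must share one alphabet")
  taxa <- sort(unique(unlist(lapply(alns, rownames))))
  widths <- vapply(alns, ncol, integer(1L))
  total <- sum(widths)
  mat <- matrix(NA_character_, length(taxa), total,
                dimnames = list(taxa, NULL))
  at <- 0L
  boundaries <- data.frame(gene = member, start = integer(length(member)),
                           end = integer(length(member)))
  for (i in seq_along(alns)) {
    w <- widths[i]
    mat[rownames(alns[[i]]), at + seq_len(w)] <- unclass(alns[[i]])
    boundaries$start[i] <- at + 1L
    boundaries$end[i] <- at + w
    at <- at + w
  }
  out <- new_alignment(mat, alpha)
  attr(out, "boundaries") <- boundaries
  out
}

#' Read per-gene alignments from a directory
#'
#' Reads every FASTA file (`.fa`, `.fas`, `.fasta`) in a directory; gene
#' names are the file names without extension, in sorted order.
#'
#' @param dir directory path.
#' @param alphabet optional shared `rcfv_alphabet`; auto-detected per file
#'   when `NULL`.
#' @return Named list of `rcfv_alignment` objects.
#' @export
read_gene_dir <- function(dir, alphabet = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fas|fasta)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no FASTA files found in %s", dir))
  genes <- lapply(files, read_alignment, format = "fasta",
                  alphabet = alphabet)
  names(genes) <- sub("\\.(fa|fas|fasta)$", "", basename(files))
  genes
}

#' Split a supermatrix by a RAxML-style partition file
#'
#' Accepts lines of the form `GENE1 = 1-2340` (1-based inclusive column
#' ranges, optionally comma-separated, optionally prefixed with a data-type
#' token such as `DNA,` or `WAG,`). Blank lines and `#` comments are
#' ignored.
#'
#' @param aln the supermatrix `rcfv_alignment`.
#' @param path path to the partition file.
#' @return Named list of `rcfv_alignment` objects, one per partition.
#' @export
split_by_partitions <- function(aln, path) {
  if (!file.exists(path)) stop(sprintf("partition file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("partition file defines no partitions")
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed partition line: '%s'", ln))
    lhs <- trimws(parts[1L])
    name <- trimws(utils::tail(strsplit(lhs, ",", fixed = TRUE)[[1L]], 1L))
    cols <- integer()
    for (rng in trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])) {
      m <- regmatches(rng, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", rng))[[1L]]
      if (length(m) == 3L) {
        lo <- as.integer(m[2L]); hi <- as.integer(m[3L])
      } else if (grepl("^[0-9]+$", rng)) {
        lo <- hi <- as.integer(rng)
      } else stop(sprintf("malformed column range '%s' in partition '%s'",
                          rng, name))
      if (lo < 1L || hi > ncol(aln) || lo > hi)
        stop(sprintf("column range %d-%d of partition '%s' is outside 1-%d",
                     lo, hi, name, ncol(aln)))
      cols <- c(cols, lo:hi)
    }
    if (name %in% names(out))
      stop(sprintf("duplicate partition name '%s'", name))
    out[[name]] <- new_alignment(unclass(aln)[, cols, drop = FALSE],
                                 alignment_alphabet(aln))
  }
  out
}
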