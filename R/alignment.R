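#' Alignment container
#'
#' An alignment is a rectangular character matrix (taxa in rows, positions in
#' columns) over a fixed alphabet, with `NA` as the missing-data sentinel.
#' Internally columns are addressed 0-based half-open; all user-facing
#' coordinates (error messages, partition files, boundary tables) are 1-based
#' inclusive.
#'
#' @param matrix character matrix of canonical states / `NA`, with unique row
#'   names (taxon labels).
#' @param alphabet an `rcfv_alphabet`.
#' @return An object of class `rcfv_alignment`: the character matrix with an
#'   `alphabet` attribute.
#' @export
new_alignment <- function(matrix, alphabet) {
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("alignment must be a character matrix")
  if (nrow(matrix) < 2L) stop("an alignment needs at least 2 taxa")
  if (ncol(matrix) < 1L) stop("an alignment needs at least 1 column")
  taxa <- trimws(rownames(matrix))
  if (is.null(taxa) || any(taxa == ""))
    stop("all taxa must be labelled")
  if (anyDuplicated(taxa))
    stop(sprintf("duplicate taxon label '%s'", taxa[duplicated(taxa)][1L]))
  rownames(matrix) <- taxa
  ok <- is.na(matrix) | matrix %in% alphabet$states
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-canonical character '%s' in taxon '%s', column %d",
                 matrix[bad[1L], bad[2L]], taxa[bad[1L]], bad[2L]))
  }
  structure(matrix, alphabet = alphabet, class = "rcfv_alignment")
}

#' @rdname new_alignment
#' @param x object to query.
#' @export
alignment_alphabet <- function(x) attr(x, "alphabet")

#' @export
print.rcfv_alignment <- function(x, ...) {
  a <- alignment_alphabet(x)
  cat(sprintf("<alignment: %d taxa x %d columns, alphabet '%s', %d missing cells>\n",
              nrow(x), ncol(x), a$name, sum(is.na(x))))
  invisible(x)
}

#' Number of taxa / columns of an alignment
#' @param aln an `rcfv_alignment`.
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname n_taxa
#' @export
n_columns <- function(aln) ncol(aln)

# Build an alignment from raw (name, sequence-string) records: canonicalize,
# enforce rectangularity and unique labels.
.alignment_from_records <- function(names, seqs, alphabet = NULL) {
  if (length(names) == 0L) stop("alignment file contains no sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf(
      "ragged alignment: taxon '%s' has %d characters where %d were expected",
      names[which(lens != lens[1L])[1L]], lens[lens != lens[1L]][1L], lens[1L]))
  if (is.null(alphabet)) alphabet <- detect_alphabet(seqs)
  rows <- lapply(seq_along(seqs), function(i)
    canonicalize(strsplit(seqs[i], "")[[1L]], alphabet, context = names[i]))
  mat <- do.call(rbind, rows)
  rownames(mat) <- names
  new_alignment(mat, alphabet)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (wrapped or unwrapped) or relaxed PHYLIP (sequential or
#' interleaved, whitespace-delimited names of any length). With
#' `format = "auto"` the file is treated as FASTA if and only if its first
#' non-blank character is `>`. Characters are upper-cased, canonicalized
#' (e.g. RNA `U` to `T`), and missing codes become the missing sentinel;
#' unrecognized characters raise an error naming taxon and column.
#'
#' @param path path to the alignment file.
#' @param format one of `"auto"`, `"fasta"`, `"phylip"`.
#' @param alphabet an `rcfv_alphabet`, or `NULL` to auto-detect with
#'   [detect_alphabet()].
#' @return An `rcfv_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    txt <- readLines(path, warn = FALSE)
    first <- txt[trimws(txt) != ""]
    if (length(first) == 0L) stop(sprintf("empty alignment file: %s", path))
    format <- if (startsWith(trimws(first[1L]), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               set.attributes = FALSE)
    .alignment_from_records(trimws(names(recs)), unlist(recs), alphabet)
  } else {
    rec <- .parse_phylip(path)
    .alignment_from_records(rec$names, rec$seqs, alphabet)
  }
}

# Relaxed PHYLIP parser. Tries a sequential token-stream parse first (names
# are whitespace tokens; sequence chunks accumulate until the header length p
# is reached), then an interleaved line parse (first block named, later
# blocks unnamed, assigned round-robin).
.parse_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) stop(sprintf("empty alignment file: %s", path))
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header: expected '<n_taxa> <n_columns>'")
  n <- as.integer(hdr[1L]); p <- as.integer(hdr[2L])
  body <- lines[-1L]

  seq_try <- tryCatch({
    toks <- unlist(strsplit(trimws(body), "\\s+"))
    nm <- character(n); sq <- character(n); k <- 1L
    for (i in seq_len(n)) {
      if (k > length(toks)) stop("truncated")
      nm[i] <- toks[k]; k <- k + 1L
      cur <- ""
      while (nchar(cur) < p) {
        if (k > length(toks)) stop("truncated")
        cur <- paste0(cur, toks[k]); k <- k + 1L
      }
      if (nchar(cur) != p) stop("overrun")
      sq[i] <- cur
    }
    if (k <= length(toks)) stop("trailing tokens")
    list(names = nm, seqs = sq)
  }, error = function(e) NULL)
  if (!is.null(seq_try)) return(seq_try)

  if (length(body) < n) stop("truncated PHYLIP file: fewer lines than taxa")
  nm <- character(n); sq <- character(n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    nm[i] <- toks[1L]
    sq[i] <- paste(toks[-1L], collapse = "")
  }
  extra <- body[-seq_len(n)]
  for (j in seq_along(extra)) {
    i <- ((j - 1L) %% n) + 1L
    sq[i] <- paste0(sq[i], gsub("\\s+", "", extra[j]))
  }
  if (any(nchar(sq) != p))
    stop(sprintf(
      "PHYLIP sequence length mismatch: taxon '%s' has %d characters, header says %d",
      nm[which(nchar(sq) != p)[1L]], nchar(sq)[nchar(sq) != p][1L], p))
  list(names = nm, seqs = sq)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' Missing cells are written as the gap character `-`. Writing then reading
#' reproduces taxa, matrix and shape exactly.
#'
#' @param aln an `rcfv_alignment`.
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  mat <- unclass(aln)
  mat[is.na(mat)] <- "-"
  seqs <- apply(mat, 1L, paste, collapse = "")
  if (format == "fasta") {
    seqinr::write.fasta(as.list(seqs), names = rownames(mat),
                        file.out = path, nbchar = 60)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
    writeLines(sprintf("%s  %s", rownames(mat), seqs), con)
  }
  invisible(path)
}
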