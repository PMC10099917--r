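#' Character-state alphabets
#'
#' An alphabet defines the canonical character states of an alignment (the
#' \eqn{c} possible states entering the metrics), the characters treated as
#' missing data, and how raw input characters are canonicalized. Missing data
#' follows the convention common in phylogenomic curation: gaps (`-`), `?`,
#' `.`, and all IUPAC ambiguity letters are classified as missing, because an
#' ambiguous residue carries no usable compositional information.
#'
#' @param name label for the alphabet (e.g. `"dna"`).
#' @param states character vector of unique single-character canonical states
#'   (at least 2).
#' @param missing_codes characters mapped to the missing sentinel (`NA`).
#' @param synonyms named character vector of extra accepted input characters
#'   mapped to canonical states (e.g. `c(U = "T")` for RNA input).
#' @return An object of class `rcfv_alphabet`: a list with elements `name`,
#'   `states`, `n_states`, `missing_codes` and `canonical_map` (a named
#'   character vector over all accepted upper-case input characters; `NA`
#'   values mark missing codes). Input is case-insensitive; lower-case
#'   variants are accepted and canonicalized to upper case.
#' @export
make_alphabet <- function(name, states, missing_codes = c("-", "?", "."),
                          synonyms = character()) {
  states <- toupper(as.character(states))
  missing_codes <- toupper(as.character(missing_codes))
  if (anyDuplicated(states)) stop("alphabet states must be unique")
  if (length(states) < 2L) stop("an alphabet needs at least 2 states")
  if (any(nchar(states) != 1L)) stop("states must be single characters")
  if (length(intersect(states, missing_codes)) > 0L)
    stop("missing codes and states must be disjoint")
  map <- c(
    stats::setNames(states, states),
    stats::setNames(rep(NA_character_, length(missing_codes)), missing_codes),
    toupper(stats::setNames(as.character(synonyms), names(synonyms)))
  )
  if (anyDuplicated(names(map)))
    stop("a character may map to at most one canonical state")
  structure(
    list(name = name, states = states, n_states = length(states),
         missing_codes = missing_codes, canonical_map = map),
    class = "rcfv_alphabet"
  )
}

# IUPAC nucleotide ambiguity letters (excluding A/C/G/T themselves)
.dna_ambiguity <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' @rdname make_alphabet
#' @export
dna_alphabet <- function() {
  make_alphabet("dna", c("A", "C", "G", "T"),
                missing_codes = c("-", "?", ".", .dna_ambiguity),
                synonyms = c(U = "T"))
}

#' @rdname make_alphabet
#' @export
protein_alphabet <- function() {
  make_alphabet("protein",
                c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                missing_codes = c("-", "?", ".", "X", "B", "Z", "J", "*"))
}

#' @export
print.rcfv_alphabet <- function(x, ...) {
  cat(sprintf("<alphabet '%s': %d states [%s]; missing codes: %s>\n",
              x$name, x$n_states, paste(x$states, collapse = ""),
              paste(x$missing_codes, collapse = "")))
  invisible(x)
}

#' Canonicalize raw characters against an alphabet
#'
#' Upper-cases the input, applies the alphabet's canonicalization map
#' (synonyms such as RNA `U` -> `T`), and converts missing codes to `NA`.
#' Canonicalization is idempotent.
#'
#' @param x character vector of single characters.
#' @param alphabet an `rcfv_alphabet`.
#' @param context optional label (e.g. taxon name) used in error messages.
#' @return character vector of canonical states with `NA` for missing cells.
#' @export
canonicalize <- function(x, alphabet, context = NULL) {
  up <- toupper(x)
  idx <- match(up, names(alphabet$canonical_map))
  bad <- which(is.na(idx))
  if (length(bad) > 0L) {
    stop(sprintf(
      "unrecognized character '%s' for alphabet '%s'%s at column %d",
      x[bad[1L]], alphabet$name,
      if (is.null(context)) "" else sprintf(" in taxon '%s'", context),
      bad[1L]))
  }
  unname(alphabet$canonical_map[idx])
}

#' Detect the alphabet of raw sequences
#'
#' Classifies sequences as nucleotide if, after upper-casing and mapping
#' `U` to `T`, every character that is not a universal missing code
#' (`-`, `?`, `.`) belongs to the IUPAC nucleotide set (A, C, G, T plus
#' ambiguity letters); otherwise as protein. Ambiguity letters count toward
#' detection but are classified as missing data by the returned alphabet.
#'
#' @param seqs character vector of raw sequence strings.
#' @return An `rcfv_alphabet` (`dna_alphabet()` or `protein_alphabet()`).
#' @export
detect_alphabet <- function(seqs) {
  chars <- unique(strsplit(toupper(paste(seqs, collapse = "")), "")[[1L]])
  chars <- setdiff(chars, c("-", "?", ".", "*"))
  chars[chars == "U"] <- "T"
  if (length(chars) == 0L)
    stop("cannot detect alphabet: all characters are missing data")
  if (all(chars %in% c("A", "C", "G", "T", .dna_ambiguity)))
    dna_alphabet()
  else
    protein_alphabet()
}
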