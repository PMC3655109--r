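#' @name iupac
#' @title IUPAC-aware sequence utilities
#' @description
#' Helpers shared across the package: reverse complement over the full IUPAC
#' nucleotide alphabet, translation in reading frame 0 with the standard
#' genetic code, and approximate pattern matching with an IUPAC-aware edit
#' distance (a degenerate code matches any base it encodes; mismatches,
#' insertions and deletions all cost 1).
NULL

IUPAC_CHARS <- "ACGTURYSWKMBDHVN"
IUPAC_COMP <- "TGCAAYRSWMKVHDBN"

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of IUPAC nucleotide strings
#'
#' @param x character vector of nucleotide sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTD") # "HACGT"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr(IUPAC_CHARS, IUPAC_COMP, toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Split sequences into codon triplets (frame 0).
codons_of <- function(x) {
  stopifnot(nchar(x) %% 3 == 0)
  substring(x, seq(1, nchar(x), by = 3), seq(3, nchar(x), by = 3))
}

genetic_code <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
}

#' Translate nucleotide sequences in reading frame 0
#'
#' @param x character vector of ACGT sequences with length divisible by 3.
#' @return character vector of amino-acid sequences (stops as `*`).
#' @export
translate_dna <- function(x) {
  gc <- genetic_code()
  vapply(x, function(s) {
    aa <- gc[codons_of(toupper(s))]
    if (anyNA(aa)) stop("sequence contains a non-ACGT codon: ", s)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

has_inframe_stop <- function(x) {
  vapply(x, function(s) any(codons_of(toupper(s)) %in% STOP_CODONS),
         logical(1), USE.NAMES = FALSE)
}

#' IUPAC-aware edit distance between two sequences
#'
#' Unit-cost Levenshtein distance where two symbols match whenever their
#' IUPAC base sets intersect (so pattern `D` matches `A`, `G` or `T`).
#'
#' @param a,b nucleotide strings (IUPAC codes allowed).
#' @return integer edit distance.
#' @export
iupac_edit_distance <- function(a, b) {
  cpp_iupac_edit(toupper(a), toupper(b))
}

#' Find the best approximate occurrence of an IUPAC pattern
#'
#' Aligns the whole `pattern` against the best-matching substring of
#' `sequence` (free endpoints in the sequence), scoring with the IUPAC-aware
#' unit-cost edit distance. Used for primer screening, where up to one
#' mismatch or indel is tolerated.
#'
#' @param pattern IUPAC nucleotide string (e.g. a degenerate primer).
#' @param sequence nucleotide string to search in.
#' @param max_edits maximum tolerated edit distance; matches beyond it are
#'   reported as a no-match.
#' @return a list with `match` (logical), `distance`, and the 1-based
#'   inclusive `start`/`end` of the matched span (NA on no-match).
#' @examples
#' match_iupac("ACDT", "ACGT", max_edits = 0) # distance 0: D covers G
#' @export
match_iupac <- function(pattern, sequence, max_edits = 1) {
  stopifnot(nchar(pattern) > 0, max_edits >= 0)
  hit <- cpp_iupac_find(toupper(pattern), toupper(sequence))
  if (hit[1] > max_edits) {
    list(match = FALSE, distance = hit[1], start = NA_integer_,
         end = NA_integer_)
  } else {
    list(match = TRUE, distance = hit[1], start = hit[2], end = hit[3])
  }
}
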