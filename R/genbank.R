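#' Fetch nucleotide sequences from GenBank by accession
#'
#' Downloads the requested accessions from NCBI efetch as FASTA. Intended
#' for pulling a study's deposited allele sequences; requires network
#' access. A local FASTA already holding the sequences can be passed to any
#' analysis function directly instead.
#'
#' @param accessions character vector of accession numbers, e.g.
#'   `genbank_accession_range("KF021627", "KF021666")`.
#' @param timeout seconds before the download attempt is abandoned.
#' @return named character vector of sequences.
#' @export
fetch_genbank_fasta <- function(accessions, timeout = 60) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=",
                paste(accessions, collapse = ","))
  dest <- tempfile(fileext = ".fasta")
  old <- getOption("timeout")
  on.exit(options(timeout = old), add = TRUE)
  options(timeout = timeout)
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0)
    stop("could not fetch sequences from GenBank (network unavailable?)")
  dna <- Biostrings::readDNAStringSet(dest)
  out <- as.character(dna)
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

#' Expand a contiguous accession range
#'
#' @param from,to first and last accession of a run sharing one letter
#'   prefix (e.g. `"KF021627"`, `"KF021666"`).
#' @return character vector of accessions.
#' @export
genbank_accession_range <- function(from, to) {
  prefix <- sub("[0-9]+$", "", from)
  stopifnot(identical(prefix, sub("[0-9]+$", "", to)))
  digits <- nchar(from) - nchar(prefix)
  nums <- as.integer(sub("^[A-Za-z]+", "", from)):as.integer(sub("^[A-Za-z]+", "", to))
  sprintf("%s%0*d", prefix, digits, nums)
}

#' Deduplicate sequences to unique alleles
#'
#' Collapses identical sequences, keeping the first name of each group.
#'
#' @param seqs named character vector of sequences.
#' @return named character vector of unique sequences.
#' @export
deduplicate_alleles <- function(seqs) {
  seqs[!duplicated(unname(seqs))]
}
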