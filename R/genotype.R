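#' @name genotype
#' @title Demultiplexing and replicate-validated allele calling
#' @description
#' Turns raw barcoded amplicon reads into per-individual allele sets.
#' Reads are screened for both primers (tolerating one mismatch or indel
#' each), assigned to an (individual, replicate) by their forward and
#' reverse MID barcodes (again within one edit), and trimmed to the insert.
#' Per individual, a distinct insert sequence is retained as an allele only
#' if (1) it appears in both independent PCR replicates and (2) its pooled
#' read frequency exceeds a threshold (default 10%) of the most frequent
#' variant's - the two filters that suppress polymerase and pyrosequencing
#' artifacts without any clustering.
NULL

#' Validate a MID barcode set for error-robust decoding
#'
#' A MID set decodes uniquely under up to `error_budget` sequencing or
#' polymerase errors per barcode iff every pairwise edit distance is at
#' least `2 * error_budget + 1`.
#'
#' @param mids character vector of equal-length barcodes.
#' @param error_budget number of per-barcode errors that must remain
#'   correctable (default 2, giving a required distance of 5).
#' @return list of class `mid_validation`: `pass`, `min_distance`,
#'   `required`, and `offending` (data frame of too-close pairs).
#' @export
validate_mid_set <- function(mids, error_budget = 2) {
  stopifnot(error_budget >= 0)
  if (length(unique(nchar(mids))) > 1) stop("MIDs must have equal length")
  required <- 2L * as.integer(error_budget) + 1L
  if (length(mids) < 2) {
    warning("fewer than 2 MIDs: uniqueness is trivial")
    return(structure(list(pass = TRUE, min_distance = NA_integer_,
                          required = required,
                          offending = data.frame(mid1 = character(0),
                                                 mid2 = character(0),
                                                 distance = integer(0))),
                     class = "mid_validation"))
  }
  pairs <- utils::combn(length(mids), 2)
  d <- apply(pairs, 2, function(p) cpp_iupac_edit(mids[p[1]], mids[p[2]]))
  bad <- which(d < required)
  offending <- data.frame(mid1 = mids[pairs[1, bad]],
                          mid2 = mids[pairs[2, bad]],
                          distance = d[bad], stringsAsFactors = FALSE)
  structure(list(pass = length(bad) == 0, min_distance = min(d),
                 required = required, offending = offending),
            class = "mid_validation")
}

#' @export
print.mid_validation <- function(x, ...) {
  cat(sprintf("MID set: min pairwise edit distance %s (required >= %d): %s\n",
              x$min_distance, x$required, if (x$pass) "PASS" else "FAIL"))
  if (!x$pass) print(x$offending)
  invisible(x)
}

# Decode one extracted MID against the sheet's MIDs. Returns the index of
# the unique MID within max_edits, or a reason string.
decode_mid <- function(observed, mids, max_edits) {
  d <- vapply(mids, function(m) cpp_iupac_edit(observed, m), integer(1))
  hits <- which(d <= max_edits)
  if (length(hits) == 0) return("unknown_mid")
  if (length(hits) > 1) return("ambiguous_mid")
  hits
}

# Attempt to parse one read in its given orientation. Returns NULL when a
# primer is not found within max_edits, else the MIDs and trimmed insert.
parse_read_one_orientation <- function(read, layout, max_edits) {
  n <- nchar(read)
  plen_f <- nchar(layout$primer_fwd)
  plen_r <- nchar(layout$primer_rev)
  win <- layout$mid_length + max_edits + 4L
  head_win <- substr(read, 1, min(n, layout$mid_length + plen_f + win))
  hit_f <- cpp_iupac_find(layout$primer_fwd, head_win)
  if (hit_f[1] > max_edits) return(NULL)
  tail_start <- max(1L, n - (layout$mid_length + plen_r + win) + 1L)
  tail_win <- substr(read, tail_start, n)
  hit_r <- cpp_iupac_find(revcomp(layout$primer_rev), tail_win)
  if (hit_r[1] > max_edits) return(NULL)
  r_start <- tail_start + hit_r[2] - 1L
  r_end <- tail_start + hit_r[3] - 1L
  if (hit_f[3] >= r_start) return(NULL)
  list(distance = hit_f[1] + hit_r[1],
       fwd_mid = substr(read, 1, hit_f[2] - 1L),
       rev_mid = revcomp(substr(read, r_end + 1L, n)),
       insert = substr(read, hit_f[3] + 1L, r_start - 1L))
}

#' Screen, demultiplex and trim amplicon reads
#'
#' A read is retained iff both primers are found (each within `max_edits`)
#' in one orientation and both MIDs decode uniquely (within `max_edits`) to
#' a sample-sheet entry that is consistent with a single (individual,
#' replicate). Everything else is discarded with a reason code:
#' `no_primer`, `unknown_mid`, `ambiguous_mid` or `conflicting_pair`.
#'
#' @param reads named character vector of reads, a `DNAStringSet`, or a path
#'   to a FASTA/FASTQ file.
#' @param sheet a sample sheet (see [make_sample_sheet()], [read_sample_sheet()]).
#' @param layout a [read_layout()].
#' @param max_edits edit tolerance for primer and MID matching (default 1,
#'   one mismatch or indel).
#' @return list of class `demux_result`: `demux` (data frame: read_id,
#'   individual, replicate, insert, orientation) and `discards` (read_id,
#'   reason).
#' @export
screen_and_demux <- function(reads, sheet, layout = read_layout(),
                             max_edits = 1) {
  validate_sample_sheet(sheet)
  reads <- as_read_vector(reads)
  rev_mids <- unique(c(sheet$rev_mid_rep1, sheet$rev_mid_rep2))
  n <- length(reads)
  ind_v <- character(n); rep_v <- integer(n); ins_v <- character(n)
  ori_v <- character(n); reason_v <- character(n)
  for (i in seq_len(n)) {
    read <- toupper(reads[[i]])
    cand <- list(fwd = parse_read_one_orientation(read, layout, max_edits),
                 rev = parse_read_one_orientation(revcomp(read), layout,
                                                  max_edits))
    cand <- Filter(Negate(is.null), cand)
    if (length(cand) == 0) { reason_v[i] <- "no_primer"; next }
    if (length(cand) == 2)
      cand <- cand[order(vapply(cand, `[[`, numeric(1), "distance"))][1]
    orientation <- names(cand)
    p <- cand[[1]]
    f_hit <- decode_mid(p$fwd_mid, sheet$fwd_mid, max_edits)
    r_hit <- decode_mid(p$rev_mid, rev_mids, max_edits)
    if (is.character(f_hit)) { reason_v[i] <- f_hit; next }
    if (is.character(r_hit)) { reason_v[i] <- r_hit; next }
    row <- sheet[f_hit, ]
    rev_mid <- rev_mids[r_hit]
    if (rev_mid == row$rev_mid_rep1) {
      replicate <- 1L
    } else if (rev_mid == row$rev_mid_rep2) {
      replicate <- 2L
    } else {
      reason_v[i] <- "conflicting_pair"; next
    }
    ind_v[i] <- row$individual
    rep_v[i] <- replicate
    ins_v[i] <- p$insert
    ori_v[i] <- orientation
  }
  ids <- names(reads) %||% sprintf("read_%06d", seq_len(n))
  kept <- reason_v == ""
  demux <- data.frame(read_id = ids[kept], individual = ind_v[kept],
                      replicate = rep_v[kept], insert = ins_v[kept],
                      orientation = ori_v[kept], stringsAsFactors = FALSE)
  discards <- data.frame(read_id = ids[!kept], reason = reason_v[!kept],
                         stringsAsFactors = FALSE)
  structure(list(demux = demux, discards = discards), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("Demultiplexed %d reads (%d discarded)\n",
              nrow(x$demux), nrow(x$discards)))
  if (nrow(x$discards) > 0) print(table(x$discards$reason))
  invisible(x)
}

#' Call the allele set of one individual
#'
#' Variants are the distinct trimmed insert sequences. A variant is retained
#' iff it is seen in both PCR replicates and its pooled read count exceeds
#' `rel_threshold` times the pooled count of the individual's most frequent
#' variant (strictly greater by default). Rejections are reported with
#' reasons `single_replicate` or `below_threshold`.
#'
#' @param demux demultiplexed reads for exactly one individual (a
#'   `demux_result`, or its `demux` data frame possibly subset).
#' @param individual id to call; required when `demux` covers several.
#' @param rel_threshold relative-frequency threshold (default 0.10).
#' @param strict if `TRUE` (default) "above threshold" is a strict
#'   inequality; set `FALSE` for >=.
#' @param reference whether the most-frequent reference variant is taken
#'   before (`"prefilter"`, default) or after (`"postfilter"`) the
#'   replicate-concordance filter.
#' @param expected_length if non-NULL, warn when a retained allele's length
#'   differs (no filtering: unexpected lengths are retained if they pass).
#' @return object of class `individual_genotype`: list with `individual`,
#'   `alleles` (data frame: sequence, count_rep1, count_rep2,
#'   pooled_frequency), `rejected` (sequence, pooled_count, reason) and
#'   `ungenotypable` flag (reads in fewer than two replicates).
#' @export
call_alleles <- function(demux, individual = NULL, rel_threshold = 0.10,
                         strict = TRUE, reference = c("prefilter", "postfilter"),
                         expected_length = NULL) {
  reference <- match.arg(reference)
  df <- if (inherits(demux, "demux_result")) demux$demux else demux
  if (!is.null(individual)) df <- df[df$individual == individual, ]
  ind <- unique(df$individual)
  if (length(ind) > 1)
    stop("reads from several individuals; pass `individual`")
  if (length(ind) == 0) ind <- individual %||% NA_character_
  empty <- data.frame(sequence = character(0), count_rep1 = integer(0),
                      count_rep2 = integer(0), pooled_frequency = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(df) == 0 || length(unique(df$replicate)) < 2) {
    vars <- unique(df$insert)
    return(structure(list(individual = ind, alleles = empty,
                          rejected = data.frame(sequence = vars,
                                                pooled_count = as.integer(
                                                  table(df$insert)[vars]),
                                                reason = rep("single_replicate",
                                                             length(vars)),
                                                stringsAsFactors = FALSE),
                          ungenotypable = TRUE),
                     class = "individual_genotype"))
  }
  tab <- table(factor(df$insert), factor(df$replicate, levels = 1:2))
  variants <- rownames(tab)
  c1 <- as.integer(tab[, 1]); c2 <- as.integer(tab[, 2])
  pooled <- c1 + c2
  in_both <- c1 >= 1 & c2 >= 1
  ref_pool <- if (reference == "prefilter" || !any(in_both)) pooled else pooled[in_both]
  ref <- max(ref_pool)
  above <- if (strict) pooled > rel_threshold * ref else pooled >= rel_threshold * ref
  keep <- in_both & above
  reason <- ifelse(!in_both, "single_replicate", "below_threshold")
  ord <- order(-pooled[keep], variants[keep])
  alleles <- data.frame(sequence = variants[keep][ord],
                        count_rep1 = c1[keep][ord], count_rep2 = c2[keep][ord],
                        pooled_frequency = pooled[keep][ord] / sum(pooled),
                        stringsAsFactors = FALSE)
  if (!is.null(expected_length)) {
    odd <- alleles$sequence[nchar(alleles$sequence) != expected_length]
    if (length(odd) > 0)
      warning(sprintf("%s: %d retained allele(s) with length != %d",
                      ind, length(odd), expected_length))
  }
  rejected <- data.frame(sequence = variants[!keep],
                         pooled_count = pooled[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(individual = ind, alleles = alleles, rejected = rejected,
                 ungenotypable = FALSE),
            class = "individual_genotype")
}

#' @export
print.individual_genotype <- function(x, ...) {
  if (x$ungenotypable) {
    cat(sprintf("%s: ungenotypable (reads in fewer than two replicates)\n",
                x$individual))
  } else {
    cat(sprintf("%s: %d allele(s) retained, %d variant(s) rejected\n",
                x$individual, nrow(x$alleles), nrow(x$rejected)))
  }
  invisible(x)
}

#' Call genotypes for every individual in a demultiplexed read set
#'
#' @inheritParams call_alleles
#' @return named list of [call_alleles()] results, class `genotype_calls`.
#' @export
call_genotypes <- function(demux, rel_threshold = 0.10, strict = TRUE,
                           reference = c("prefilter", "postfilter"),
                           expected_length = NULL) {
  reference <- match.arg(reference)
  df <- if (inherits(demux, "demux_result")) demux$demux else demux
  inds <- sort(unique(df$individual))
  out <- lapply(inds, function(i)
    call_alleles(df[df$individual == i, ], rel_threshold = rel_threshold,
                 strict = strict, reference = reference,
                 expected_length = expected_length))
  names(out) <- inds
  structure(out, class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  n_alleles <- vapply(x, function(g) nrow(g$alleles), integer(1))
  cat(sprintf("Genotypes for %d individuals (%d ungenotypable)\n",
              length(x), sum(vapply(x, `[[`, logical(1), "ungenotypable"))))
  cat("Alleles per individual:\n")
  print(table(n_alleles))
  invisible(x)
}

#' Summarize the population allele pool
#'
#' Collapses per-individual calls into a population allele table. The
#' carrier proportion of an allele is the number of individuals carrying it
#' divided by the number of successfully genotyped individuals (those with
#' at least one retained allele; empty individuals are excluded from the
#' denominator with a warning). Allele ids are assigned by decreasing
#' carrier count, ties broken by sequence, so identical input yields
#' identical ids.
#'
#' @param genotypes a [call_genotypes()] result.
#' @return object of class `population_table`: data frame (allele_id,
#'   sequence, carriers, proportion, singleton) with attribute
#'   `n_genotyped`.
#' @export
build_population_table <- function(genotypes) {
  stopifnot(length(genotypes) >= 1)
  called <- Filter(function(g) nrow(g$alleles) > 0, genotypes)
  if (length(called) < length(genotypes))
    warning(sprintf("%d individual(s) with no retained alleles excluded ",
                    length(genotypes) - length(called)),
            "from the carrier denominator")
  if (length(called) == 0) stop("no genotyped individuals")
  seqs <- unlist(lapply(called, function(g) unique(g$alleles$sequence)),
                 use.names = FALSE)
  counts <- table(seqs)
  ord <- order(-as.integer(counts), names(counts))
  sequence <- names(counts)[ord]
  carriers <- as.integer(counts)[ord]
  out <- data.frame(allele_id = sprintf("allele_%02d", seq_along(sequence)),
                    sequence = sequence, carriers = carriers,
                    proportion = carriers / length(called),
                    singleton = carriers == 1L, stringsAsFactors = FALSE)
  attr(out, "n_genotyped") <- length(called)
  class(out) <- c("population_table", "data.frame")
  out
}

#' Compare called genotypes with a simulation truth set
#'
#' Matches called allele sequences against each individual's true allele
#' sequences and reports per-individual true/false positives and misses,
#' plus micro-averaged precision and recall over all individuals.
#'
#' @param calls a [call_genotypes()] result.
#' @param genotypes a truth table from [assign_genotypes()].
#' @param pool the allele pool the truth refers to.
#' @return list with `per_individual` (data frame: individual, tp, fp, fn)
#'   and overall `precision` and `recall`.
#' @export
genotype_accuracy <- function(calls, genotypes, pool) {
  truth <- split(genotypes$allele_id, genotypes$individual)
  rows <- lapply(names(truth), function(ind) {
    true_seqs <- unname(pool$alleles[truth[[ind]]])
    called <- if (ind %in% names(calls)) calls[[ind]]$alleles$sequence else character(0)
    tp <- sum(called %in% true_seqs)
    data.frame(individual = ind, tp = tp, fp = length(called) - tp,
               fn = length(true_seqs) - tp, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_individual = per,
       precision = sum(per$tp) / max(1L, sum(per$tp) + sum(per$fp)),
       recall = sum(per$tp) / max(1L, sum(per$tp) + sum(per$fn)))
}

as_read_vector <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE)) "fastq" else "fasta"
    dna <- Biostrings::readDNAStringSet(reads, format = fmt)
    reads <- as.character(dna)
  } else if (methods::is(reads, "DNAStringSet")) {
    reads <- as.character(reads)
  }
  stopifnot(is.character(reads))
  reads
}

#' Read a sample sheet TSV
#'
#' Expects a header line `individual fwd_mid rev_mid_rep1 rev_mid_rep2`.
#'
#' @param path path to a tab-separated file.
#' @return a validated `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Write genotype call tables
#'
#' Writes `genotypes.tsv` (individual, allele_id, counts, pooled frequency),
#' `alleles.fasta`, `population.tsv` and `discards.tsv` in the conventional
#' pipeline layout.
#'
#' @param calls a [call_genotypes()] result.
#' @param demux the matching `demux_result` (for the discard log); optional.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_genotypes <- function(calls, demux = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- build_population_table(calls)
  id_of <- stats::setNames(pop$allele_id, pop$sequence)
  rows <- lapply(calls, function(g) {
    if (nrow(g$alleles) == 0) return(NULL)
    data.frame(individual = g$individual,
               allele_id = unname(id_of[g$alleles$sequence]),
               count_rep1 = g$alleles$count_rep1,
               count_rep2 = g$alleles$count_rep2,
               pooled_frequency = g$alleles$pooled_frequency,
               stringsAsFactors = FALSE)
  })
  geno <- do.call(rbind, rows)
  rownames(geno) <- NULL
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             alleles = file.path(dir, "alleles.fasta"),
             population = file.path(dir, "population.tsv"),
             discards = file.path(dir, "discards.tsv"))
  utils::write.table(geno, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fa <- Biostrings::DNAStringSet(stats::setNames(pop$sequence, pop$allele_id))
  Biostrings::writeXStringSet(fa, paths["alleles"])
  utils::write.table(as.data.frame(pop)[, c("allele_id", "carriers", "proportion")],
                     paths["population"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(demux))
    utils::write.table(demux$discards, paths["discards"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(paths)
}
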