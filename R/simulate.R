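#' @name simulate
#' @title Synthetic 454-style MHC amplicon study generator
#' @description
#' Generates the three layers of a barcoded amplicon genotyping study with a
#' known truth: an allele pool (equal-length, in-frame, stop-free nucleotide
#' alleles), per-individual genotypes of 1-4 distinct alleles, and barcoded
#' pyrosequencing-style reads carrying substitution errors, homopolymer
#' slippage indels and PCR chimeras. Each individual is amplified in two
#' independent PCR replicates that share a forward MID barcode but differ in
#' the reverse MID, which is what the replicate-concordance genotype filter
#' exploits downstream.
NULL

#' Amplicon read layout
#'
#' Fixed structural elements of a barcoded amplicon read: emulsion-PCR
#' adaptors (not emitted by default), 10-nt MID barcodes, and the degenerate
#' class I exon 2 primer pair. Reads are laid out as
#' `fwd MID + fwd primer + insert + revcomp(rev primer) + revcomp(rev MID)`.
#'
#' @param adaptor_fwd,adaptor_rev library adaptor sequences (prepended only
#'   when `include_adaptors = TRUE` in [simulate_reads()]).
#' @param mid_length barcode length in nucleotides.
#' @param primer_fwd,primer_rev amplification primers, IUPAC codes allowed.
#' @return an object of class `read_layout`.
#' @export
read_layout <- function(adaptor_fwd = "CCATCTCATCCCTGCGTGTCTCCGACTCAG",
                        adaptor_rev = "CCTATCCCCTGTGTGCCTTGGCAGTCTCAG",
                        mid_length = 10L,
                        primer_fwd = "GATGTATGGGTGTGATCTCCGGG",
                        primer_rev = "TTCACTCGATGCAGGTCDNCTCCAGGT") {
  stopifnot(mid_length >= 1)
  ok <- grepl(sprintf("^[%s]+$", IUPAC_CHARS), toupper(c(primer_fwd, primer_rev)))
  if (!all(ok)) stop("primers must contain only IUPAC nucleotide codes")
  structure(list(adaptor_fwd = toupper(adaptor_fwd),
                 adaptor_rev = toupper(adaptor_rev),
                 mid_length = as.integer(mid_length),
                 primer_fwd = toupper(primer_fwd),
                 primer_rev = toupper(primer_rev)),
            class = "read_layout")
}

#' Sequencing and PCR error model
#'
#' @param substitution_rate per-base probability of a random substitution.
#' @param homopolymer_indel_rate per-homopolymer-run (length >= 2)
#'   probability of a one-base slip; an insertion duplicates the run base,
#'   a deletion removes one copy.
#' @param chimera_rate per-read probability that the template is a
#'   two-parent recombinant of the individual's alleles with a uniform
#'   breakpoint (only possible when the individual carries >= 2 alleles).
#' @param reads_per_replicate mean read count per individual per PCR
#'   replicate (Poisson).
#' @return an object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.005,
                        homopolymer_indel_rate = 0.01,
                        chimera_rate = 0.03,
                        reads_per_replicate = 60) {
  rates <- c(substitution_rate, homopolymer_indel_rate, chimera_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), reads_per_replicate >= 1)
  structure(list(substitution_rate = substitution_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 chimera_rate = chimera_rate,
                 reads_per_replicate = reads_per_replicate),
            class = "error_model")
}

#' Population sampling design
#'
#' @param n_individuals number of individuals to genotype.
#' @param copies_prob sampling distribution of the per-individual allele
#'   count; names give the supported counts. The default puts its median at
#'   2 copies with support 1-4, the range seen in multi-locus MHC class I
#'   amplicon studies.
#' @param allele_weights sampling weights over pool alleles; `NULL` means a
#'   geometric spectrum (ratio 0.9) so a few alleles are common and many are
#'   rare.
#' @return an object of class `population_design`.
#' @export
population_design <- function(n_individuals = 40L,
                              copies_prob = c("1" = 0.20, "2" = 0.35,
                                              "3" = 0.30, "4" = 0.15),
                              allele_weights = NULL) {
  stopifnot(n_individuals >= 1, all(copies_prob >= 0), sum(copies_prob) > 0)
  support <- as.integer(names(copies_prob))
  if (anyNA(support) || any(support < 1))
    stop("copies_prob must be named by positive integer allele counts")
  if (!is.null(allele_weights))
    stopifnot(all(allele_weights >= 0), sum(allele_weights) > 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 copies_prob = copies_prob / sum(copies_prob),
                 allele_weights = allele_weights),
            class = "population_design")
}

# Mutate one sequence away from an ancestor. Each site mutates with
# probability `divergence`; a proposed change is rejected if it creates an
# in-frame stop, and otherwise accepted with probability min(1, 1/omega) if
# synonymous and min(1, omega) if nonsynonymous, so omega > 1 enriches
# amino-acid-changing substitutions.
mutate_sequence <- function(ancestor, divergence, omega = 1) {
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  s <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  sites <- which(stats::runif(length(s)) < divergence)
  a_syn <- min(1, 1 / omega)
  a_non <- min(1, omega)
  for (i in sites) {
    new_base <- sample(setdiff(bases, s[i]), 1)
    cod_idx <- (i - 1) %/% 3
    cod_pos <- cod_idx * 3 + 1:3
    old_codon <- paste(s[cod_pos], collapse = "")
    cand <- s
    cand[i] <- new_base
    new_codon <- paste(cand[cod_pos], collapse = "")
    if (new_codon %in% STOP_CODONS) next
    acc <- if (gc[[old_codon]] == gc[[new_codon]]) a_syn else a_non
    if (stats::runif(1) < acc) s[i] <- new_base
  }
  paste(s, collapse = "")
}

random_stopfree_sequence <- function(length) {
  gc <- genetic_code()
  non_stop <- setdiff(names(gc), STOP_CODONS)
  paste(sample(non_stop, length %/% 3, replace = TRUE), collapse = "")
}

#' Generate a synthetic allele pool
#'
#' Draws a random stop-free ancestor and derives `n_alleles` distinct,
#' in-frame, stop-free alleles from it by per-site mutation. `omega` biases
#' accepted mutations towards nonsynonymous changes, mimicking the excess of
#' amino-acid variation that balancing selection maintains at MHC loci
#' (`omega = 1` is neutral). Duplicates and stop-bearing draws are resampled.
#'
#' @param n_alleles pool size (the field study scale is ~34).
#' @param length allele length in bp; must be divisible by 3. Default 216,
#'   the class I exon 2 amplicon insert length.
#' @param divergence per-site mutation probability from the ancestor. The
#'   default 0.085 yields a mean pairwise divergence of ~16% (about 34
#'   differences over 216 bp).
#' @param seed RNG seed; identical inputs and seed give byte-identical pools.
#' @param omega nonsynonymous/synonymous acceptance ratio during mutation.
#' @param max_tries resampling budget per allele before giving up.
#' @return object of class `allele_pool`: list with `alleles` (named
#'   character vector) and `ids`.
#' @export
generate_allele_pool <- function(n_alleles = 34L, length = 216L,
                                 divergence = 0.085, seed = NULL,
                                 omega = 1, max_tries = 1000L) {
  if (length %% 3 != 0) stop("allele length must be divisible by 3")
  stopifnot(length >= 3, n_alleles >= 1, divergence >= 0, divergence <= 1)
  if (log(n_alleles) > length * log(4))
    stop("n_alleles exceeds the number of distinct sequences of this length")
  with_seed(seed, {
    ancestor <- random_stopfree_sequence(length)
    alleles <- character(0)
    for (k in seq_len(n_alleles)) {
      for (try in seq_len(max_tries)) {
        cand <- mutate_sequence(ancestor, divergence, omega)
        if (!has_inframe_stop(cand) && !(cand %in% alleles)) break
        cand <- NULL
      }
      if (is.null(cand))
        stop("could not generate a distinct stop-free allele; ",
             "raise divergence or max_tries")
      alleles[k] <- cand
    }
    ids <- sprintf("allele_%02d", seq_len(n_alleles))
    names(alleles) <- ids
    structure(list(alleles = alleles, ids = ids, length = as.integer(length)),
              class = "allele_pool")
  })
}

#' @export
print.allele_pool <- function(x, ...) {
  cat(sprintf("Allele pool: %d alleles of %d bp (in-frame, stop-free)\n",
              length(x$alleles), x$length))
  invisible(x)
}

#' Assign true genotypes to individuals
#'
#' Each individual receives a set of distinct alleles: the set size is drawn
#' from the design's `copies_prob` and the alleles from its frequency
#' spectrum (without replacement within an individual).
#'
#' @param pool an [generate_allele_pool()] result.
#' @param design a [population_design()].
#' @param seed RNG seed.
#' @return data frame of class `truth_genotypes` with columns `individual`
#'   and `allele_id`, one row per carried allele.
#' @export
assign_genotypes <- function(pool, design = population_design(), seed = NULL) {
  stopifnot(inherits(pool, "allele_pool"), inherits(design, "population_design"))
  support <- as.integer(names(design$copies_prob))
  if (max(support[design$copies_prob > 0]) > length(pool$ids))
    stop("design requests more allele copies than the pool contains")
  w <- design$allele_weights %||% (0.9 ^ seq_along(pool$ids))
  if (length(w) != length(pool$ids))
    stop("allele_weights length must equal the pool size")
  with_seed(seed, {
    rows <- lapply(seq_len(design$n_individuals), function(i) {
      k <- support[sample.int(length(support), 1, prob = design$copies_prob)]
      ids <- sample(pool$ids, k, prob = w)
      data.frame(individual = sprintf("ind_%03d", i), allele_id = ids,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("truth_genotypes", "data.frame")
    out
  })
}

#' Generate a sample sheet of MID barcodes
#'
#' Draws random MID barcodes whose pairwise edit distances are all at least
#' `min_distance` (default 5 = 2 x 2 + 1), so any read carrying up to two
#' polymerase/sequencing errors in its MID still decodes to the right
#' individual. Each individual gets a unique forward MID; the two PCR
#' replicates are distinguished by two shared reverse MIDs.
#'
#' @param individuals character vector of individual ids, or a single count.
#' @param mid_length barcode length.
#' @param min_distance minimum pairwise edit distance across all MIDs.
#' @param seed RNG seed.
#' @return data frame of class `sample_sheet` with columns `individual`,
#'   `fwd_mid`, `rev_mid_rep1`, `rev_mid_rep2`.
#' @export
make_sample_sheet <- function(individuals, mid_length = 10L,
                              min_distance = 5L, seed = NULL) {
  if (is.numeric(individuals) && length(individuals) == 1)
    individuals <- sprintf("ind_%03d", seq_len(individuals))
  n_mids <- length(individuals) + 2L
  with_seed(seed, {
    mids <- character(0)
    tries <- 0L
    while (length(mids) < n_mids) {
      cand <- paste(sample(c("A", "C", "G", "T"), mid_length, replace = TRUE),
                    collapse = "")
      ok <- all(vapply(mids, function(m) cpp_iupac_edit(m, cand),
                       integer(1)) >= min_distance)
      if (ok) mids <- c(mids, cand)
      tries <- tries + 1L
      if (tries > 10000L * n_mids)
        stop("could not build a MID set at this length/distance")
    }
    out <- data.frame(individual = individuals,
                      fwd_mid = mids[seq_along(individuals)],
                      rev_mid_rep1 = mids[n_mids - 1L],
                      rev_mid_rep2 = mids[n_mids],
                      stringsAsFactors = FALSE)
    class(out) <- c("sample_sheet", "data.frame")
    out
  })
}

validate_sample_sheet <- function(sheet) {
  need <- c("individual", "fwd_mid", "rev_mid_rep1", "rev_mid_rep2")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$individual)) stop("duplicate individual ids")
  if (anyDuplicated(sheet$fwd_mid)) stop("forward MIDs must be unique")
  pairs <- c(paste(sheet$fwd_mid, sheet$rev_mid_rep1),
             paste(sheet$fwd_mid, sheet$rev_mid_rep2))
  if (anyDuplicated(pairs)) stop("(forward, reverse) MID pairs must be unique")
  lens <- nchar(c(sheet$fwd_mid, sheet$rev_mid_rep1, sheet$rev_mid_rep2))
  if (length(unique(lens)) != 1) stop("all MIDs must have equal length")
  invisible(sheet)
}

# One realization of a degenerate primer: each IUPAC position is sampled
# uniformly among the bases it encodes, as PCR with degenerate primers
# yields a mix of products.
realize_primer <- function(primer) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) {
    set <- IUPAC_SETS[[c]]
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  list(seq = paste(s, collapse = ""), n = length(hit))
}

# Homopolymer slippage: each run of >= 2 identical bases slips with
# probability `rate`, gaining or losing one copy of the run base (50/50).
apply_homopolymer_slips <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(s)
  n_events <- 0L
  pieces <- character(length(r$lengths))
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    if (len >= 2 && stats::runif(1) < rate) {
      len <- len + sample(c(-1L, 1L), 1)
      n_events <- n_events + 1L
    }
    pieces[k] <- strrep(r$values[k], len)
  }
  list(seq = paste(pieces, collapse = ""), n = n_events)
}

#' Simulate barcoded amplicon reads with a truth set
#'
#' Assembles one read per amplicon molecule as
#' `fwd MID + fwd primer + template + revcomp(rev primer) + revcomp(rev MID)`
#' where the template is one of the individual's true alleles or, with
#' probability `chimera_rate`, a two-parent PCR chimera with a uniform
#' breakpoint. Substitution and homopolymer-slip errors are applied to the
#' assembled read, and every read's provenance (individual, replicate,
#' template, error events) is recorded.
#'
#' @param genotypes a [assign_genotypes()] truth table.
#' @param pool the [generate_allele_pool()] the genotypes refer to.
#' @param sheet a [make_sample_sheet()] covering every individual.
#' @param layout a [read_layout()].
#' @param errmodel an [error_model()].
#' @param seed RNG seed.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented
#'   (pyrosequencing reads either strand; the demultiplexer must cope).
#' @param include_adaptors prepend/append library adaptors (off by default:
#'   reads start at the MID, matching the demultiplexer contract).
#' @return object of class `amplicon_sim`: list with `reads` (named
#'   character vector) and `provenance` (data frame: read_id, individual,
#'   replicate, template, breakpoint, n_subs, n_indels, revcomp).
#' @export
simulate_reads <- function(genotypes, pool, sheet, layout = read_layout(),
                           errmodel = error_model(), seed = NULL,
                           revcomp_fraction = 0, include_adaptors = FALSE) {
  stopifnot(inherits(pool, "allele_pool"))
  validate_sample_sheet(sheet)
  inds <- unique(genotypes$individual)
  missing <- setdiff(inds, sheet$individual)
  if (length(missing) > 0)
    stop("individuals missing from the sample sheet: ",
         paste(missing, collapse = ", "))
  geno_list <- split(genotypes$allele_id, genotypes$individual)
  with_seed(seed, {
    reads <- character(0)
    prov <- vector("list", length(inds) * 2L)
    slot <- 0L
    read_no <- 0L
    for (ind in inds) {
      alleles <- geno_list[[ind]]
      row <- sheet[sheet$individual == ind, ]
      for (rep in 1:2) {
        rev_mid <- if (rep == 1) row$rev_mid_rep1 else row$rev_mid_rep2
        n_reads <- max(1L, stats::rpois(1, errmodel$reads_per_replicate))
        recs <- vector("list", n_reads)
        for (r in seq_len(n_reads)) {
          read_no <- read_no + 1L
          rid <- sprintf("read_%06d", read_no)
          is_chimera <- length(alleles) >= 2 &&
            stats::runif(1) < errmodel$chimera_rate
          if (is_chimera) {
            parents <- sample(alleles, 2)
            bp <- sample.int(pool$length - 1L, 1)
            template <- paste0(substr(pool$alleles[[parents[1]]], 1, bp),
                               substr(pool$alleles[[parents[2]]], bp + 1,
                                      pool$length))
            template_lab <- sprintf("%s|%s@%d", parents[1], parents[2], bp)
          } else {
            a <- if (length(alleles) == 1) alleles else sample(alleles, 1)
            template <- pool$alleles[[a]]
            template_lab <- a
            bp <- NA_integer_
          }
          read <- paste0(row$fwd_mid, realize_primer(layout$primer_fwd),
                         template,
                         revcomp(realize_primer(layout$primer_rev)),
                         revcomp(rev_mid))
          sub <- apply_substitutions(read, errmodel$substitution_rate)
          slip <- apply_homopolymer_slips(sub$seq,
                                          errmodel$homopolymer_indel_rate)
          read <- slip$seq
          if (include_adaptors)
            read <- paste0(layout$adaptor_fwd, read,
                           revcomp(layout$adaptor_rev))
          rc <- revcomp_fraction > 0 && stats::runif(1) < revcomp_fraction
          if (rc) read <- revcomp(read)
          reads[rid] <- read
          recs[[r]] <- data.frame(read_id = rid, individual = ind,
                                  replicate = rep, template = template_lab,
                                  breakpoint = bp, n_subs = sub$n,
                                  n_indels = slip$n, revcomp = rc,
                                  stringsAsFactors = FALSE)
        }
        slot <- slot + 1L
        prov[[slot]] <- do.call(rbind, recs)
      }
    }
    provenance <- do.call(rbind, prov)
    rownames(provenance) <- NULL
    structure(list(reads = reads, provenance = provenance),
              class = "amplicon_sim")
  })
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf("Amplicon simulation: %d reads from %d individuals\n",
              length(x$reads), length(unique(x$provenance$individual))))
  cat(sprintf("  chimeric reads: %d; mean substitutions/read: %.2f\n",
              sum(grepl("|", x$provenance$template, fixed = TRUE)),
              mean(x$provenance$n_subs)))
  invisible(x)
}

#' Write simulated reads and truth files
#'
#' Writes reads as FASTA or FASTQ (constant placeholder qualities; the
#' pipeline never uses them), the allele pool FASTA, and the two truth TSVs
#' (`genotypes.tsv`, `provenance.tsv`).
#'
#' @param sim an [simulate_reads()] result.
#' @param genotypes the matching truth genotypes.
#' @param pool the allele pool.
#' @param dir output directory (created if needed).
#' @param format `"fasta"` or `"fastq"` for the reads.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, genotypes, pool, dir, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads_path <- file.path(dir, paste0("reads.", format))
  dna <- Biostrings::DNAStringSet(sim$reads)
  if (format == "fasta") {
    Biostrings::writeXStringSet(dna, reads_path)
  } else {
    q <- Biostrings::BStringSet(strrep("I", nchar(sim$reads)))
    Biostrings::writeXStringSet(dna, reads_path, format = "fastq", qualities = q)
  }
  pool_path <- file.path(dir, "pool.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pool$alleles), pool_path)
  geno_path <- file.path(dir, "genotypes.tsv")
  utils::write.table(genotypes, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov_path <- file.path(dir, "provenance.tsv")
  utils::write.table(sim$provenance, prov_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(reads = reads_path, pool = pool_path, genotypes = geno_path,
              provenance = prov_path))
}

#' Simulate a codon alignment under a given dN/dS regime
#'
#' Star-phylogeny codon evolution used for power and type-I calibration of
#' the selection Z-test: every sequence descends independently from a common
#' stop-free ancestor, with nonsynonymous changes accepted `omega` times
#' more readily than synonymous ones.
#'
#' @param n_seq number of sequences.
#' @param n_codons alignment length in codons.
#' @param divergence per-site mutation probability from the ancestor.
#' @param omega nonsynonymous/synonymous acceptance ratio (1 = neutral).
#' @param seed RNG seed.
#' @return named character vector of equal-length ACGT sequences.
#' @export
simulate_selection_alignment <- function(n_seq, n_codons, divergence = 0.05,
                                         omega = 1, seed = NULL) {
  with_seed(seed, {
    anc <- random_stopfree_sequence(n_codons * 3L)
    seqs <- vapply(seq_len(n_seq),
                   function(i) mutate_sequence(anc, divergence, omega),
                   character(1))
    names(seqs) <- sprintf("seq_%02d", seq_len(n_seq))
    seqs
  })
}

#' Simulate morphometrics with a quadratic condition-diversity effect
#'
#' Generates curved carapace width (CCW) and length (CCL) for individuals
#' whose body condition (the CCL-on-CCW residual) depends on their MHC
#' allele count through `intercept + lin * k + quad * k^2` plus Gaussian
#' noise. Defaults place the optimum at an intermediate allele count
#' (concave quadratic, coefficient -0.194) with noise calibrated so the
#' quadratic model explains ~16% of condition variance under the default
#' 1-4 allele-count spectrum.
#'
#' @param allele_counts named integer vector (names = individual ids).
#' @param quad,lin,intercept quadratic, linear and intercept coefficients of
#'   the condition-on-count relation (cm).
#' @param noise_sd residual SD of condition (cm).
#' @param ccw_mean,ccw_sd population CCW distribution (cm); nesting
#'   loggerhead females are typically 70-80 cm across.
#' @param ccl_slope,ccl_intercept structural CCL-on-CCW relation (cm).
#' @param seed RNG seed.
#' @return data frame of class `morphometrics` with columns `individual`,
#'   `ccl`, `ccw`.
#' @export
simulate_morphometrics <- function(allele_counts, quad = -0.194, lin = 0.091,
                                   intercept = -0.0413, noise_sd = 1.98,
                                   ccw_mean = 75, ccw_sd = 4,
                                   ccl_slope = 1.08, ccl_intercept = 5,
                                   seed = NULL) {
  stopifnot(length(allele_counts) >= 1, all(allele_counts >= 1))
  ids <- names(allele_counts) %||% sprintf("ind_%03d", seq_along(allele_counts))
  with_seed(seed, {
    n <- length(allele_counts)
    ccw <- stats::rnorm(n, ccw_mean, ccw_sd)
    condition <- intercept + lin * allele_counts + quad * allele_counts^2 +
      stats::rnorm(n, 0, noise_sd)
    ccl <- ccl_intercept + ccl_slope * ccw + condition
    out <- data.frame(individual = ids, ccl = ccl, ccw = ccw,
                      stringsAsFactors = FALSE)
    class(out) <- c("morphometrics", "data.frame")
    out
  })
}
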