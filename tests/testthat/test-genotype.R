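test_that("match_iupac agrees with the IUPAC table and an edit-distance oracle", {
  expect_equal(match_iupac("ACGT", "ACGT", max_edits = 1)$distance, 0)
  # D covers A/G/T
  expect_equal(match_iupac("ACDT", "ACGT", max_edits = 0)$distance, 0)
  hit <- match_iupac("ACGT", "AGGA", max_edits = 1)
  expect_false(hit$match)
  expect_equal(hit$distance, 2)
  expect_error(match_iupac("ACXT", "ACGT"), "non-nucleotide")
  # random ACGT cases against a plain DP oracle (IUPAC reduces to equality)
  set.seed(1)
  for (k in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE), collapse = "")
    expect_equal(iupac_edit_distance(a, b), oracle_edit_distance(a, b))
  }
})

test_that("match_iupac locates the matched span in a longer sequence", {
  hit <- match_iupac("CCGG", "AAAACCGGTTTT", max_edits = 0)
  expect_equal(c(hit$start, hit$end), c(5, 8))
  # one deletion inside the pattern occurrence
  hit2 <- match_iupac("CCAGG", "AAAACCGGTTTT", max_edits = 1)
  expect_true(hit2$match)
  expect_equal(hit2$distance, 1)
})

test_that("MID set validation enforces the 2e+1 decoding radius", {
  expect_true(validate_mid_set(c("AAAAAAAAAA", "TTTTTTTTTT"))$pass)
  expect_true(validate_mid_set(c("AAAAAAAAAA", "AAAATTTTTT"))$pass)   # d = 6
  v <- validate_mid_set(c("AAAAAAAAAA", "AAAAAATTTT"))                # d = 4
  expect_false(v$pass)
  expect_equal(v$min_distance, 4L)
  expect_equal(nrow(v$offending), 1L)
  expect_warning(validate_mid_set("AAAAAAAAAA"), "fewer than 2")
  # generated sample sheets satisfy the guarantee by construction
  sheet <- make_sample_sheet(10, seed = 3)
  mids <- c(sheet$fwd_mid, sheet$rev_mid_rep1[1], sheet$rev_mid_rep2[1])
  expect_true(validate_mid_set(mids, error_budget = 2)$pass)
})

test_that("allele calling applies the replicate and threshold filters literally", {
  # worked case: C only in replicate 1
  dx <- demux_from_counts(c(AAA = 50, CCC = 30, GGG = 4), c(AAA = 60, CCC = 25))
  g <- call_alleles(dx)
  expect_setequal(g$alleles$sequence, c("AAA", "CCC"))
  expect_equal(g$rejected$reason[g$rejected$sequence == "GGG"],
               "single_replicate")
  # worked case: pooled 17 vs 195 is 8.7% <= 10%
  g2 <- call_alleles(demux_from_counts(c(AAA = 100, CCC = 9),
                                       c(AAA = 95, CCC = 8)))
  expect_identical(g2$alleles$sequence, "AAA")
  expect_equal(g2$rejected$reason[g2$rejected$sequence == "CCC"],
               "below_threshold")
  # exactly 10% is not "above 10%" under the strict default
  g3 <- call_alleles(demux_from_counts(c(AAA = 50, CCC = 5),
                                       c(AAA = 50, CCC = 5)))
  expect_identical(g3$alleles$sequence, "AAA")
  expect_setequal(call_alleles(demux_from_counts(c(AAA = 50, CCC = 5),
                                                 c(AAA = 50, CCC = 5)),
                               strict = FALSE)$alleles$sequence,
                  c("AAA", "CCC"))
  # single shared variant
  g4 <- call_alleles(demux_from_counts(c(AAA = 3), c(AAA = 2)))
  expect_identical(g4$alleles$sequence, "AAA")
  expect_equal(g4$alleles$count_rep1, 3L)
  expect_equal(g4$alleles$count_rep2, 2L)
})

test_that("reads in a single replicate leave the individual ungenotypable", {
  g <- call_alleles(demux_from_counts(c(AAA = 100, CCC = 50), integer(0)))
  expect_true(g$ungenotypable)
  expect_equal(nrow(g$alleles), 0L)
})

test_that("raising the threshold never adds alleles", {
  set.seed(4)
  for (rep in 1:20) {
    vars <- paste0("V", 1:6)
    r1 <- setNames(rpois(6, 20), vars)[sample(6, 4)]
    r2 <- setNames(rpois(6, 20), vars)[sample(6, 4)]
    dx <- demux_from_counts(r1[r1 > 0], r2[r2 > 0])
    prev <- Inf
    for (thr in c(0, 0.05, 0.1, 0.25, 0.5)) {
      n <- nrow(call_alleles(dx, rel_threshold = thr)$alleles)
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("single-replicate artifacts are never retained regardless of abundance", {
  dx <- demux_from_counts(c(AAA = 5, TTT = 500), c(AAA = 5))
  g <- call_alleles(dx)
  expect_false("TTT" %in% g$alleles$sequence)
  expect_equal(g$rejected$reason[g$rejected$sequence == "TTT"],
               "single_replicate")
  # with the prefilter reference the artifact also drags AAA below 10% of
  # the (artifactual) modal variant; the postfilter reference keeps it
  expect_equal(g$rejected$reason[g$rejected$sequence == "AAA"],
               "below_threshold")
  expect_identical(call_alleles(dx, reference = "postfilter")$alleles$sequence,
                   "AAA")
})

test_that("population table reports carrier proportions over genotyped individuals", {
  mk <- function(ind, seqs) call_alleles(demux_from_counts(
    setNames(rep(10, length(seqs)), seqs),
    setNames(rep(10, length(seqs)), seqs), individual = ind), individual = ind)
  calls <- list(i1 = mk("i1", c("AAA", "CCC")), i2 = mk("i2", "AAA"),
                i3 = mk("i3", c("AAA", "GGG")), i4 = mk("i4", "AAA"))
  class(calls) <- "genotype_calls"
  pop <- build_population_table(calls)
  expect_equal(pop$proportion[pop$sequence == "AAA"], 1.0)
  expect_equal(pop$proportion[pop$sequence == "CCC"], 0.25)
  expect_true(all(pop$singleton == (pop$carriers == 1)))
  # ungenotypable individuals drop out of the denominator with a warning
  calls$i5 <- call_alleles(demux_from_counts(c(TTT = 4), integer(0),
                                             individual = "i5"))
  expect_warning(pop2 <- build_population_table(calls), "excluded")
  expect_equal(pop2$proportion[pop2$sequence == "CCC"], 0.25)
  # ids are stable on identical input
  expect_identical(pop$allele_id, suppressWarnings(
    build_population_table(calls[1:4])$allele_id))
})

test_that("error-free simulated reads demultiplex and recover genotypes exactly", {
  pool <- generate_allele_pool(8, 30, 0.25, seed = 21)
  geno <- assign_genotypes(pool, population_design(6), seed = 21)
  sheet <- make_sample_sheet(unique(geno$individual), seed = 21)
  sim <- simulate_reads(geno, pool, sheet, errmodel = error_model(0, 0, 0, 15),
                        seed = 21, revcomp_fraction = 0.5)
  dx <- screen_and_demux(sim$reads, sheet)
  expect_equal(nrow(dx$discards), 0L)
  prov <- sim$provenance[match(dx$demux$read_id, sim$provenance$read_id), ]
  expect_identical(dx$demux$individual, prov$individual)
  expect_identical(dx$demux$replicate, prov$replicate)
  acc <- genotype_accuracy(call_genotypes(dx), geno, pool)
  expect_equal(acc$precision, 1)
  expect_equal(acc$recall, 1)
})

test_that("demultiplexing is invariant to read order and strand", {
  pool <- generate_allele_pool(4, 30, 0.25, seed = 23)
  geno <- assign_genotypes(pool, population_design(4), seed = 23)
  sheet <- make_sample_sheet(unique(geno$individual), seed = 23)
  sim <- simulate_reads(geno, pool, sheet, errmodel = error_model(0.01, 0.01, 0, 8),
                        seed = 23)
  canon <- function(dx) {
    d <- dx$demux[order(dx$demux$read_id), c("read_id", "individual",
                                             "replicate", "insert")]
    rownames(d) <- NULL
    d
  }
  dx1 <- screen_and_demux(sim$reads, sheet)
  dx2 <- screen_and_demux(sim$reads[rev(seq_along(sim$reads))], sheet)
  expect_identical(canon(dx1), canon(dx2))
  flipped <- setNames(revcomp(sim$reads), names(sim$reads))
  dx3 <- screen_and_demux(flipped, sheet)
  expect_identical(canon(dx1), canon(dx3))
})

test_that("demux discards carry the right reason codes", {
  sheet <- make_sample_sheet(2, seed = 31)
  layout <- read_layout()
  pool <- generate_allele_pool(1, 30, 0, seed = 31)
  mk_read <- function(fwd_mid, rev_mid) paste0(
    fwd_mid, chartr("DN", "GA", layout$primer_fwd), pool$alleles[[1]],
    revcomp(chartr("DN", "GA", layout$primer_rev)), revcomp(rev_mid))
  good <- mk_read(sheet$fwd_mid[1], sheet$rev_mid_rep1[1])
  dx <- screen_and_demux(c(r1 = good), sheet)
  expect_identical(dx$demux$individual, sheet$individual[1])
  # two substitutions in the forward primer (read positions 11-12 are "GA")
  bad_primer <- good
  substr(bad_primer, 11, 12) <- "CC"
  expect_identical(screen_and_demux(c(r = bad_primer), sheet)$discards$reason,
                   "no_primer")
  # a MID absent from the sheet (far from every entry)
  far_mid <- strrep("A", 10)
  while (min(vapply(c(sheet$fwd_mid), iupac_edit_distance, integer(1),
                    a = far_mid)) <= 1) far_mid <- strrep("C", 10)
  unknown <- mk_read(far_mid, sheet$rev_mid_rep1[1])
  expect_identical(screen_and_demux(c(r = unknown), sheet)$discards$reason,
                   "unknown_mid")
  # one substitution in the MID still decodes (distance 1 unique)
  one_err <- mk_read(sub("^.", if (substr(sheet$fwd_mid[2], 1, 1) == "A") "C"
                         else "A", sheet$fwd_mid[2]), sheet$rev_mid_rep2[2])
  dx2 <- screen_and_demux(c(r = one_err), sheet)
  expect_identical(dx2$demux$individual, sheet$individual[2])
  expect_identical(dx2$demux$replicate, 2L)
})
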