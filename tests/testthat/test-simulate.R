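test_that("allele pools satisfy their invariants across sizes and seeds", {
  cases <- list(list(n = 1, L = 6, div = 0),
                list(n = 10, L = 30, div = 0.2),
                list(n = 34, L = 216, div = 0.1))
  for (cs in cases) {
    pool <- generate_allele_pool(cs$n, cs$L, cs$div, seed = 1)
    expect_length(pool$alleles, cs$n)
    expect_true(all(nchar(pool$alleles) == cs$L))
    expect_false(any(has_inframe_stop(pool$alleles)))
    expect_equal(anyDuplicated(pool$alleles), 0L)
    expect_true(all(grepl("^[ACGT]+$", pool$alleles)))
  }
  expect_identical(generate_allele_pool(5, 30, 0.1, seed = 42),
                   generate_allele_pool(5, 30, 0.1, seed = 42))
  expect_error(generate_allele_pool(3, 4), "divisible")
  expect_error(generate_allele_pool(300, 3), "distinct sequences")
})

test_that("genotype assignment respects the copies distribution", {
  pool1 <- generate_allele_pool(1, 6, 0, seed = 1)
  g1 <- assign_genotypes(pool1, population_design(5, c("1" = 1)), seed = 1)
  expect_true(all(table(g1$individual) == 1))
  expect_true(all(g1$allele_id == pool1$ids))

  pool <- generate_allele_pool(8, 30, 0.2, seed = 2)
  g2 <- assign_genotypes(pool, population_design(12, c("2" = 1)), seed = 3)
  per <- table(g2$individual)
  expect_true(all(per == 2))
  expect_false(any(tapply(g2$allele_id, g2$individual, anyDuplicated) > 0))

  g3 <- assign_genotypes(pool, population_design(40), seed = 7)
  counts <- table(g3$individual)
  expect_true(all(counts >= 1 & counts <= 4))
  expect_true(median(counts) %in% 1:4)
  expect_error(assign_genotypes(pool1, population_design(3, c("2" = 1))),
               "more allele copies")
})

test_that("error-free reads carry the exact allele insert and full provenance", {
  pool <- generate_allele_pool(4, 30, 0.2, seed = 5)
  geno <- assign_genotypes(pool, population_design(4, c("2" = 1)), seed = 5)
  sheet <- make_sample_sheet(unique(geno$individual), seed = 5)
  sim <- simulate_reads(geno, pool, sheet, errmodel = error_model(0, 0, 0, 10),
                        seed = 5)
  expect_setequal(sim$provenance$read_id, names(sim$reads))
  expect_equal(anyDuplicated(sim$provenance$read_id), 0L)
  layout <- read_layout()
  truth <- split(geno$allele_id, geno$individual)
  for (k in seq_along(sim$reads)) {
    prov <- sim$provenance[k, ]
    read <- sim$reads[[prov$read_id]]
    row <- sheet[sheet$individual == prov$individual, ]
    expect_identical(substr(read, 1, 10), row$fwd_mid)
    rev_mid <- if (prov$replicate == 1) row$rev_mid_rep1 else row$rev_mid_rep2
    expect_identical(substr(read, nchar(read) - 9, nchar(read)),
                     revcomp(rev_mid))
    insert <- substr(read, 10 + nchar(layout$primer_fwd) + 1,
                     nchar(read) - 10 - nchar(layout$primer_rev))
    expect_identical(insert, unname(pool$alleles[[prov$template]]))
    expect_true(prov$template %in% truth[[prov$individual]])
  }
})

test_that("forced chimeras are two-parent breakpoint concatenations", {
  pool <- generate_allele_pool(2, 30, 0.3, seed = 9)
  geno <- data.frame(individual = rep("ind_001", 2), allele_id = pool$ids)
  class(geno) <- c("truth_genotypes", "data.frame")
  sheet <- make_sample_sheet("ind_001", seed = 9)
  sim <- simulate_reads(geno, pool, sheet, errmodel = error_model(0, 0, 1, 15),
                        seed = 9)
  expect_true(all(grepl("|", sim$provenance$template, fixed = TRUE)))
  layout <- read_layout()
  for (k in seq_along(sim$reads)) {
    prov <- sim$provenance[k, ]
    parts <- strsplit(sub("@.*", "", prov$template), "|", fixed = TRUE)[[1]]
    bp <- prov$breakpoint
    expected <- paste0(substr(pool$alleles[[parts[1]]], 1, bp),
                       substr(pool$alleles[[parts[2]]], bp + 1, 30))
    read <- sim$reads[[prov$read_id]]
    insert <- substr(read, 10 + nchar(layout$primer_fwd) + 1,
                     nchar(read) - 10 - nchar(layout$primer_rev))
    expect_identical(insert, expected)
    expect_true(bp >= 1 && bp <= 29)
  }
})

test_that("substitution errors hit at the configured per-base rate", {
  pool <- generate_allele_pool(3, 216, 0.1, seed = 11)
  geno <- assign_genotypes(pool, population_design(10, c("2" = 1)), seed = 11)
  sheet <- make_sample_sheet(unique(geno$individual), seed = 11)
  rate <- 0.01
  sim <- simulate_reads(geno, pool, sheet,
                        errmodel = error_model(rate, 0, 0, 40), seed = 11)
  n_bases <- sum(nchar(sim$reads))
  # substitutions may revert nothing (always change the base), so the
  # recorded event count is binomial(n_bases, rate)
  observed <- sum(sim$provenance$n_subs) / n_bases
  se <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(observed - rate), 3 * se)
})

test_that("simulation is deterministic given a seed and reports slips in runs", {
  pool <- generate_allele_pool(3, 30, 0.2, seed = 13)
  geno <- assign_genotypes(pool, population_design(3, c("1" = 1)), seed = 13)
  sheet <- make_sample_sheet(unique(geno$individual), seed = 13)
  s1 <- simulate_reads(geno, pool, sheet, seed = 99)
  s2 <- simulate_reads(geno, pool, sheet, seed = 99)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$provenance, s2$provenance)
  # a read's length changes only via homopolymer slips
  slip <- simulate_reads(geno, pool, sheet,
                         errmodel = error_model(0, 0.5, 0, 10), seed = 7)
  base_len <- nchar(simulate_reads(geno, pool, sheet,
                                   errmodel = error_model(0, 0, 0, 1),
                                   seed = 7)$reads[[1]])
  delta <- nchar(slip$reads) - base_len
  expect_true(all(abs(delta) <= slip$provenance$n_indels))
})

test_that("written simulation files round-trip through standard parsers", {
  dir <- withr::local_tempdir()
  pool <- generate_allele_pool(3, 30, 0.2, seed = 17)
  geno <- assign_genotypes(pool, population_design(3, c("1" = 1)), seed = 17)
  sheet <- make_sample_sheet(unique(geno$individual), seed = 17)
  sim <- simulate_reads(geno, pool, sheet, errmodel = error_model(0, 0, 0, 5),
                        seed = 17)
  paths <- write_simulation(sim, geno, pool, dir, format = "fastq")
  back <- Biostrings::readDNAStringSet(paths["reads"], format = "fastq")
  expect_identical(as.character(back), sim$reads)
  prov <- read.delim(paths["provenance"])
  expect_equal(nrow(prov), length(sim$reads))
})
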