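test_that("pairwise differences match hand counts at both levels", {
  al <- c(a = "AAATTT", b = "AAATTT")
  expect_equal(pairwise_differences(al)$matrix["a", "b"], 0L)
  al2 <- c(a = "AAATTT", b = "AAATTA")  # TTT Phe -> TTA Leu
  expect_equal(pairwise_differences(al2)$matrix["a", "b"], 1L)
  expect_equal(pairwise_differences(al2, "amino_acid")$matrix["a", "b"], 1L)
  # three sequences with pairwise nt diffs {1, 2, 3}
  al3 <- c(x = "AAATTT", y = "AAATTA", z = "AAAGGT")
  d <- pairwise_differences(al3)
  expect_equal(sort(d$matrix[lower.tri(d$matrix)]), c(1L, 2L, 3L))
  expect_equal(unname(d$summary["median"]), 2)
  expect_equal(unname(d$summary["mean"]), 2)
  expect_true(isSymmetric(d$matrix))
  expect_true(all(diag(d$matrix) == 0))
})

test_that("translation commutes with codon-wise column subsetting", {
  set.seed(2)
  al <- simulate_selection_alignment(5, 12, divergence = 0.3, seed = 2)
  keep_codons <- c(1L, 3L, 7L, 10L)
  nt_idx <- as.vector(vapply(keep_codons, function(k) (k - 1L) * 3L + 1:3,
                             integer(3)))
  sub_nt <- vapply(al, function(s)
    paste(strsplit(s, "")[[1]][nt_idx], collapse = ""), character(1))
  expect_identical(translate_dna(sub_nt),
                   vapply(translate_dna(al), function(a)
                     paste(strsplit(a, "")[[1]][keep_codons], collapse = ""),
                     character(1), USE.NAMES = FALSE))
})

test_that("Nei-Gojobori matches the frozen worked example", {
  r <- nei_gojobori(c(a = "ATGGCT", b = "ATGGAT"))
  p <- r$pairs
  expect_equal(p$S, 2 / 3, tolerance = 1e-12)
  expect_equal(p$N, 16 / 3, tolerance = 1e-12)
  expect_equal(p$sd, 0)
  expect_equal(p$nd, 1)
  expect_equal(p$pN, 0.1875, tolerance = 1e-12)
  expect_equal(p$dN, -0.75 * log(1 - 4 * 0.1875 / 3), tolerance = 1e-12)
  expect_equal(p$dS, 0)
})

test_that("identical sequences give a no-test sentinel", {
  r <- nei_gojobori(c(a = "ATGGCT", b = "ATGGCT"))
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$Z))
  expect_message(zt <- ztest_positive_selection(r), "no test")
  expect_true(is.na(zt$Z) && is.na(zt$p))
})

test_that("saturated pairs are flagged and excluded from overall means", {
  # GGA vs GGC: S = 1 per sequence, sd = 1, pS = 1 >= 3/4
  expect_warning(r <- nei_gojobori(c(a = "GGAATGTTT", b = "GGCATGTTT",
                                     c = "GGAATGTTT")),
                 "p >= 3/4")
  expect_equal(r$n_excluded, 2L)
  expect_equal(r$n_pairs, 1L)
})

test_that("site and pathway counting equals exhaustive enumeration", {
  set.seed(7)
  c1 <- random_codons(500)
  c2 <- random_codons(500)
  for (k in seq_len(500)) {
    al <- c(a = c1[k], b = c2[k])
    r <- suppressWarnings(nei_gojobori(al, correction = "none"))
    S_exp <- (oracle_syn_sites(c1[k]) + oracle_syn_sites(c2[k])) / 2
    path <- oracle_path_counts(c1[k], c2[k])
    expect_equal(r$pairs$S, S_exp, tolerance = 1e-9)
    expect_equal(r$pairs$sd, unname(path["sd"]), tolerance = 1e-9)
    expect_equal(r$pairs$nd, unname(path["nd"]), tolerance = 1e-9)
    expect_equal(r$pairs$S + r$pairs$N, 3, tolerance = 1e-9)
  }
})

test_that("S + N equals the alignment length for every pair", {
  al <- simulate_selection_alignment(6, 20, divergence = 0.15, omega = 2,
                                     seed = 3)
  r <- suppressWarnings(nei_gojobori(al))
  expect_true(all(abs(r$pairs$S + r$pairs$N - 60) < 1e-9))
})

test_that("the Z-test detects a forced nonsynonymous excess", {
  set.seed(11)
  hits <- replicate(40, {
    al <- simulate_selection_alignment(30, 36, divergence = 0.06, omega = 5)
    suppressWarnings(nei_gojobori(al))$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("residue variability matches pair-counting arithmetic", {
  # invariant column -> 0; all-distinct column -> 1 (equal weights)
  al <- c(a = "GCTAAA", b = "GCTCCC", c = "GCTGGG", d = "GCTTGG")
  v <- residue_variability(al, weighting = "equal")
  expect_equal(v$variability[1], 0)
  expect_equal(v$variability[2], 1)
  # A,A,A,T column: conservation 3/6
  v2 <- residue_variability(c(a = "GCT", b = "GCT", c = "GCT", d = "ACT"),
                            weighting = "equal")
  expect_equal(v2$variability[1], 0.5)
  expect_true(all(v2$variability >= 0 & v2$variability <= 1))
})

test_that("variability is order-invariant and duplicates are downweighted", {
  al <- simulate_selection_alignment(6, 15, divergence = 0.2, omega = 3,
                                     seed = 5)
  v1 <- residue_variability(al)$variability
  v2 <- residue_variability(al[sample(length(al))])$variability
  expect_equal(v1, v2, tolerance = 1e-12)
  # duplicating a sequence shrinks its relative distance-based weight
  # (the copy contributes zero distance to it), and invariant columns stay 0
  dup <- c(al, dup1 = unname(al[1]))
  rv1 <- residue_variability(al)
  rv3 <- residue_variability(dup)
  w1 <- attr(rv1, "weights"); w3 <- attr(rv3, "weights")
  expect_lt(w3[["seq_01"]] / w3[["seq_02"]], w1[["seq_01"]] / w1[["seq_02"]])
  expect_equal(w3[["seq_01"]], w3[["dup1"]], tolerance = 1e-12)
  expect_true(all(rv3$variability >= 0 & rv3$variability <= 1))
  expect_true(all(rv3$variability[v1 == 0] == 0))
})

test_that("external residue numbering offset shifts reported sites", {
  al <- c(a = "GCTAAA", b = "GCTCCC")
  v <- residue_variability(al, offset = 120L)
  expect_equal(v$external_site, c(121L, 122L))
  expect_equal(v$column, 1:2)
})

test_that("alignment validation rejects malformed input", {
  expect_error(as_allele_alignment(c("ACGACG", "ACG")), "equal length")
  expect_error(as_allele_alignment(c("ACGA", "ACGT")), "divisible by 3")
  expect_error(as_allele_alignment(c("ACGANT", "ACGTTT")), "only A, C, G, T")
  expect_error(nei_gojobori(c(a = "TAAGGG", b = "TAAGGC")), "stop codons")
})
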