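# ampliMHC

Replicate-validated genotyping of highly polymorphic immune-gene amplicons
and the molecular-evolution statistics that typically follow, in one
tested R package.

Classical MHC population screens amplify a hypervariable exon (here, the
class I exon 2 encoding part of the peptide-binding α1 domain) from many
individuals at once, tagging each PCR with a 10-nt multiplex identifier
(MID) barcode and pooling everything on a 454-style long-read amplicon
run. Two artifacts dominate such data: single-base indels in homopolymer
tracts and PCR chimeras. The pipeline implemented here suppresses both
without any clustering, using only experimental design: every individual
is amplified in **two independent PCR replicates** that share a forward
MID but differ in the reverse MID, and a sequence variant is accepted as
an allele only if

1. it appears in **both** replicates, and
2. its pooled read count is **above 10%** of the individual's most
   frequent variant (threshold configurable, strict `>` by default).

The package provides, as plain R functions:

- **Simulation** (`generate_allele_pool`, `assign_genotypes`,
  `make_sample_sheet`, `simulate_reads`): synthetic allele pools
  (equal-length, in-frame, stop-free; optionally evolved with a
  nonsynonymous excess ω), individuals carrying 1–4 alleles, and barcoded
  reads with substitution errors, homopolymer slips and chimeras — plus a
  machine-readable truth set for benchmarking.
- **Genotyping** (`screen_and_demux`, `call_alleles`, `call_genotypes`,
  `build_population_table`, `validate_mid_set`): primer screening and MID
  demultiplexing with an IUPAC-aware edit distance (one mismatch *or*
  indel tolerated, reason-coded discards), trimming, the two-filter allele
  caller, and population allele tables. `validate_mid_set` checks the
  design rule that MIDs decode uniquely under up to *e* errors iff all
  pairwise edit distances are ≥ 2*e* + 1.
- **Selection statistics** (`pairwise_differences`, `nei_gojobori`,
  `ztest_positive_selection`, `residue_variability`): Nei–Gojobori (1986)
  dN/dS with Jukes–Cantor correction, d = −(3/4)·log(1 − 4p/3), a
  one-tailed Z-test of dN > dS, and per-residue variability
  y = 1 − (weighted sum-of-pairs conservation).
- **Recombination & linkage** (`four_gamete_rm`, `geneconv_scan`,
  `ld_randomization`): the Hudson–Kaplan four-gamete lower bound RM on
  recombination events, a gene-conversion scan for unusually long shared
  tracts judged by column-permutation tests, and the standardized index of
  association r̄d with a column-shuffling randomization test.
- **Phylogenetics** (`jc_distance`, `nj_tree`, `bootstrap_support`):
  Saitou–Nei neighbor joining with deterministic tie-breaking and
  nonparametric bootstrap bipartition support, returned as `ape::phylo`.
- **Fitness proxy** (`body_condition`, `quadratic_fit`): body condition as
  the residual of curved carapace length on curved carapace width, and its
  quadratic association with individual allele count (a negative quadratic
  term indicates an optimum at intermediate MHC diversity).

## Worked example

Simulate a 12-individual study with realistic 454-style error rates, call
genotypes, and run the downstream statistics on the called alleles:

```r
library(ampliMHC)

pool  <- generate_allele_pool(n_alleles = 12, length = 216, seed = 7, omega = 3)
geno  <- assign_genotypes(pool, population_design(n_individuals = 12), seed = 8)
sheet <- make_sample_sheet(unique(geno$individual), seed = 9)
sim   <- simulate_reads(geno, pool, sheet, errmodel = error_model(), seed = 10)

demux <- screen_and_demux(sim$reads, sheet)
#> Demultiplexed 1406 reads (41 discarded)
#>   no_primer unknown_mid
#>          31          10
calls <- call_genotypes(demux)
genotype_accuracy(calls, geno, pool)[c("precision", "recall")]
#> precision    recall
#>     0.906     0.967

pop <- build_population_table(calls)
al  <- as_allele_alignment(setNames(pop$sequence, pop$allele_id)[nchar(pop$sequence) == 216])
pairwise_differences(al)
#> Pairwise nucleotide differences over 13 sequences:
#>    min    max median   mean     sd
#>   1.00  37.00  26.50  26.23   5.85
nei_gojobori(al)
#> Nei-Gojobori over 78 pairs (jukes-cantor correction):
#>   dN = 0.1584, dS = 0.0584, dN/dS = 2.714
#>   Z = 18.074, one-tailed p (dN > dS) = 2.569e-73
four_gamete_rm(al)
#> Hudson-Kaplan RM = 4 (13 incompatible site pairs)
ld_randomization(presence_matrix(calls), n_randomizations = 1000, seed = 11)
#> LD over 15 loci: r_bar_d = -0.0116 (IA = -0.1593), p = 0.6803 (1000 randomizations)
```

Reading the output: the demultiplexer discarded 41 reads whose primers or
MIDs could not be matched within one edit; the caller recovered the true
allele sets with 90.6% precision and 96.7% recall (the residual false
positives are recurring homopolymer-slip variants that survive both
filters at this depth); the called pool shows a strong nonsynonymous
excess (dN/dS ≈ 2.7, as simulated with ω = 3), a minimum of 4
recombination events in its history, and no multilocus linkage
disequilibrium among alleles (p ≈ 0.68), as expected for independently
assigned genotypes.

The pool under positive selection (ω > 1) mimics balancing selection on
peptide-binding residues; with the defaults the alleles diverge ~16% per
site, similar to an MHC class I exon pool. See the methods vignette
(`vignettes/amplicon-mhc-methods.Rmd`) for the model details, parameter
choices and limitations.

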