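---
title: "Methods: replicate-validated MHC amplicon genotyping and its downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-validated MHC amplicon genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions behind `ampliMHC`, in the order data flows through the
package: read simulation, demultiplexing and allele calling, then the
divergence, selection, recombination, linkage, phylogeny and fitness
statistics. It also states explicitly what the synthetic-data generator
does and does not emulate, and therefore what a passing test suite does
and does not show about real data.

## The study design being modelled

A barcoded amplicon survey of a single hypervariable immune-gene exon
(MHC class I exon 2, 216 bp insert) across a population. Each individual
is amplified in two independent PCR replicates; both share the
individual's forward MID barcode (10 nt) but carry different reverse
MIDs, so every read can be traced to an (individual, replicate) pair.
Reads have the layout

```
fwd MID + fwd primer + insert + revcomp(rev primer) + revcomp(rev MID)
```

with the emulsion-PCR adaptors already removed (an option prepends them
for robustness testing). Because MHC loci are commonly duplicated,
individuals carry one to four distinct alleles across up to four loci;
the caller makes no assumption about locus number and imposes no cap.

## Read simulation

`generate_allele_pool()` draws a stop-free random ancestor and mutates
each site independently with probability `divergence` per derived allele.
Defaults: 34 alleles of 216 bp, `divergence = 0.085`, which gives a mean
pairwise divergence of about 16% (~34 differences over 216 bp), typical
of an MHC class I allele pool. The optional `omega` parameter accepts
proposed nonsynonymous changes `omega` times more readily than synonymous
ones (mutations creating in-frame stops are always rejected), so pools
can be evolved with the nonsynonymous excess that balancing selection
maintains at peptide-binding sites; `omega = 1` is neutral.

Because every allele descends independently from one ancestor (a star
phylogeny), the pool has *no tree structure*: pairwise distances
concentrate around their mean rather than spanning the near-identical to
highly-diverged range of a real allele genealogy. Tests that pass on
these pools therefore validate the statistics' arithmetic and
calibration, not their behaviour on deeply structured genealogies; the
neighbor-joining and bootstrap machinery is instead validated on additive
matrices from random trees, where exact recovery is provable.

`assign_genotypes()` draws each individual's allele count from
`copies_prob` (default 0.20/0.35/0.30/0.15 over 1–4 copies, median 2)
and its alleles without replacement from a geometric frequency spectrum
(ratio 0.9), so a few alleles are common and many are singletons, as in
real MHC surveys. `simulate_reads()` then emits, per individual and
replicate, a Poisson number of reads (mean `reads_per_replicate`,
default 60 — raw depth is rarely reported for such studies, so this is a
package choice, not an observed value) and applies, in order:

* **chimeras** — with probability `chimera_rate` (default 0.03) the
  template is a two-parent recombinant of the individual's alleles with a
  uniformly placed breakpoint, emulating template switching during PCR;
* **substitutions** — each base flips to a uniformly chosen other base
  with probability `substitution_rate` (default 0.005);
* **homopolymer slips** — each run of two or more identical bases gains
  or loses one copy of the run base with probability
  `homopolymer_indel_rate` (default 0.01 per run, direction 50/50), the
  characteristic pyrosequencing error mode. Slips are deterministic in
  outcome (duplicate or delete the run base), so a given slip variant
  *recurs identically* across reads and replicates — an important
  property for interpreting the caller's error rates (below).

Degenerate primer positions are realized per read by sampling uniformly
among the IUPAC-allowed bases, as degenerate-primer PCR yields mixed
products. FASTQ qualities are constant placeholders; nothing downstream
uses them. There is no flowgram-level signal model, no per-allele PCR
efficiency bias, and no quality-score realism.

## Demultiplexing and allele calling

Primer and MID matching use a unit-cost edit distance in which a
degenerate IUPAC code matches every base it encodes. A read is kept iff
both primers are found, each within `max_edits` (default 1: one mismatch
*or* indel), in one orientation — both strands are tried — and both MIDs
decode to a unique sample-sheet entry within the same tolerance,
consistently with a single (individual, replicate). Failures are logged
with reason codes (`no_primer`, `unknown_mid`, `ambiguous_mid`,
`conflicting_pair`) rather than raised.

MID sets are generated so that all pairwise edit distances are at least
5 = 2×2 + 1, which guarantees unique nearest-MID decoding under up to two
polymerase/sequencing errors; `validate_mid_set()` checks this for any
set. Decoding nonetheless accepts only distance ≤ 1 by default (the
screening tolerance); the radius is configurable.

`call_alleles()` treats each distinct trimmed insert string as a variant
— deliberately *no* clustering, length filtering or stop-codon filtering,
so the two experimental filters carry the entire error-suppression
burden. A variant is retained iff

1. it has at least one read in each replicate, and
2. its pooled count (both replicates) is strictly above `rel_threshold`
   (default 0.10) times the pooled count of the individual's most
   frequent variant.

Three conventions were genuinely open and are resolved as follows, each
configurable: the criterion-2 frequency is computed on **pooled** counts
(matching "proportion of reads within the individual"); "above 10%" is a
**strict** inequality; and the reference variant is the top variant
**before** filtering (`reference = "postfilter"` switches to the
filtered top — note that with the prefilter reference, a massive
single-replicate artifact can drag genuine low-copy alleles below
threshold).

**What accuracy to expect.** With the default error rates and 60
reads/replicate, only ~23% of reads carry an error-free insert, so at
this depth an individual's modal variant has roughly 14 exact copies and
the 10% threshold sits near pooled count 1.4. Recurring deterministic
homopolymer-slip variants that happen to appear once in each replicate
(pooled count 2) therefore pass both filters at a rate of roughly 0.3–0.5
false alleles per individual: measured over ten simulation seeds, recall
is ~0.97 but precision ~0.91. Deeper sequencing or lower indel rates move
the threshold above the double-singleton level and precision rises
accordingly; with error-free reads recovery is exact. This behaviour is a
property of the two-filter design at this depth, not of the
implementation.

Individuals whose retained set is empty are excluded from the
population-table denominator (an assay failure is indistinguishable from
true absence); allele identifiers are assigned by decreasing carrier
count then sequence, so identical input yields identical ids.

## Divergence and selection statistics

`pairwise_differences()` reports Hamming counts over all unordered pairs
at the nucleotide or (frame-0 translated) amino-acid level, with the
summary over lower-triangle values.

`nei_gojobori()` implements the Nei–Gojobori (1986) unweighted-pathway
method: synonymous site counts per codon by the 1/3-fraction rule
(changes to stop codons count as nonsynonymous, so S + N equals the
sequence length), observed synonymous/nonsynonymous differences averaged
over all minimal mutational pathways per codon pair with
stop-traversing pathways excluded (if every pathway hits a stop, all are
averaged as a fallback), proportions pS = sd/S and pN = nd/N, and the
Jukes–Cantor correction d = −(3/4)·log(1 − 4p/3). Pairs with p ≥ 3/4 are
outside the correction's domain and are excluded from the overall means
with a warning. The overall dN and dS are unweighted means over valid
pairs, with delta-method variances Var(d) = p(1−p)/(sites·(1−4p/3)²)
summed as if pairs were independent — the classical "overall average"
codon Z-test. Z = (dN − dS)/√(Var dN + Var dS) is tested one-tailed
against N(0, 1).

Treating the n(n−1)/2 pairwise comparisons as independent understates the
variance of the means for n > 2, which makes the test anticonservative as
a *population* test but is the standard form of this statistic; its
type-I calibration is therefore checked at n = 2, where the variance is
exact, and its power under a forced nonsynonymous excess (ω = 5, 30
sequences) at the many-sequence scale.

`residue_variability()` computes, per amino-acid column, a weighted
sum-of-pairs conservation score with an identity similarity matrix by
default (a normalized substitution matrix can be supplied) and sequence
weights proportional to each sequence's mean distance from the others, a
Valdar-style weighting that down-weights clusters of near-duplicates;
variability is y = 1 − conservation, 0 for invariant columns, 1 for
all-distinct columns under equal weights. Duplicating a sequence shrinks
its relative weight by the factor 1/(1 + d/S) — this, rather than any
global monotonicity of y (which does not hold: re-weighting can raise
variability at columns where the non-duplicated sequences disagree), is
the guarantee the weighting provides and the property the tests assert.
A reporting `offset` lets sites be quoted in an external
residue-numbering frame.

## Recombination, gene conversion, linkage

`four_gamete_rm()`: a pair of biallelic segregating sites showing all
four gametes is incompatible with an infinite-sites genealogy and demands
a recombination breakpoint strictly between the sites. RM is the size of
a minimum set of breakpoints hitting every incompatible open interval,
found by the classical sort-by-right-endpoint greedy stabbing, which is
optimal for intervals; the certifying disjoint intervals are reported.
Sites with more than two states are excluded. Note that adjacent
incompatible pairs (sites 1–2 and 2–3) define disjoint open intervals
and therefore count two events.

`geneconv_scan()` looks for unusually long stretches of agreement between
sequence pairs given their overall polymorphism. Restricted to
polymorphic columns, a pair's inner fragments are its maximal runs of
agreement and its score is the longest run (in polymorphic sites; no
mismatch-penalized extension by default). The null permutes the *order*
of the polymorphic columns — one shuffle applied to all sequences per
replicate — preserving every pairwise agreement total while destroying
positional clustering. Because integer run lengths tie heavily,
replicates are ranked against the observation by the full sorted
run-length profile, lexicographically, and the add-one p-value counts
strictly better replicates: ties favour the observed arrangement. This
keeps the null rejection rate of the pairwise test near nominal
(measured ~0.06 at the 5% level on i.i.d. columns) while a pair agreeing
at every polymorphic site — which no permutation can beat — attains the
minimum attainable p of 1/(n_permutations + 1). Fewer than three
polymorphic sites yield a no-test sentinel; only alignment-internal
fragments are considered.

`ld_randomization()` measures multilocus association among allele
presence/absence columns with the standardized index of association r̄d
(sample-size independent; the raw IA is reported alongside). The null
shuffles each column independently across individuals, preserving allele
frequencies while breaking between-locus association; the p-value is the
add-one fraction of randomizations with r̄d at least as large as
observed. Monomorphic columns are dropped; fewer than two polymorphic
columns yield a no-test sentinel.

All permutation and randomization tests take explicit seeds and are
bit-reproducible; add-one counting means no reported p is ever zero.

## Phylogenetics

Distances are Jukes–Cantor by default (consistent with the dN/dS
correction; p-distance is available). A saturated pair (p ≥ 3/4) is an
error in the point estimate. `nj_tree()` is a direct Saitou–Nei
implementation: the Q-criterion, ties broken by the earliest (row,
column) pair so results are deterministic, negative branch-length
estimates clamped to zero with the clamped total recorded in an
attribute. On additive matrices it provably recovers the generating
topology and path lengths (tested on random trees up to 8 taxa).

`bootstrap_support()` resamples alignment columns with replacement;
each internal edge of the point tree is labelled with the percentage of
replicate trees containing the same bipartition. Saturated pairs inside a
replicate are not dropped (that would bias support): they are assigned
the replicate's maximum finite distance plus rank-preserving increments
ordered by p-distance. Newick export uses 6-decimal branch lengths with
integer support percentages as internal node labels.

## The fitness proxy

Body condition is the residual of an OLS regression of curved carapace
length on curved carapace width (both in cm) — a size-corrected condition
measure, motivated by the link between female size and clutch size in sea
turtles. `quadratic_fit()` regresses condition on the individual allele
count and its square (raw counts by default, so the fitted equation reads
directly in allele units; centring is available), reporting coefficients,
two-sided p-values and R². A negative quadratic coefficient places the
condition optimum at intermediate MHC diversity.

`simulate_morphometrics()` generates data under this model for recovery
testing. Defaults: CCW ~ N(75, 4) cm (nesting loggerhead females),
structural CCL = 5 + 1.08·CCW, condition effect
−0.0413 + 0.091·k − 0.194·k², and residual SD 1.98 cm, chosen so the
quadratic model explains ≈ 16% of condition variance under the default
1–4 allele-count spectrum — an effect size representative of
MHC-diversity/condition associations in reptiles. Coefficient recovery
is unbiased (500-replicate check) and the quadratic p-value is uniform
under a null effect.

## Problem sizes used by the tests and the acceptance script

The test suite exercises: exact recovery at zero error rates; the
realistic-error round trip at the full study scale (34 alleles, 40
individuals, 60 reads/replicate, 10 seeds); oracle equivalence for the
Nei–Gojobori counts (500 random codon pairs vs recursive pathway
enumeration), RM (200 random alignments with ≤ 8 segregating sites vs
exhaustive minimum-breakpoint search) and NJ (100 random additive
matrices, ≤ 8 taxa); and statistical calibration (Z-test type-I at n = 2
over 500 neutral replicates, power at ω = 5; LD and gene-conversion null
rejection on shuffled data; quadratic-coefficient recovery over 500
replicates). `scripts/acceptance.R` runs the full pipeline once at study
scale with 10,000 permutation/randomization replicates and 1000
bootstrap replicates, all seeded from `--seed`.

## Known limitations

* The star-phylogeny pool generator produces no deep allelic lineages;
  lineage-level phenomena (trans-species-polymorphism-like clustering,
  very close allele pairs) are under-represented in synthetic data.
* The caller's precision at default depth is bounded by recurring
  homopolymer-slip doubletons, as quantified above.
* The gene-conversion scan is a simplified inner-fragment max-run test:
  no mismatch-penalized fragment extension, no outer-sequence fragments,
  and no replication of any particular binary's scoring constants.
* The overall-average dN/dS Z-test inherits the classical independence
  approximation across pairs; for inference on many sequences its p-value
  should be read as a descriptive index rather than a calibrated
  population test.
* No likelihood or Bayesian tree inference, and no codon-model (ω-class
  mixture) site tests; positive selection is assessed by the Z-test and
  per-residue variability only.
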