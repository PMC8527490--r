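---
title: "Detecting and simulating homoeologous exchange in neoallotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and simulating homoeologous exchange in neoallotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A newly induced allotetraploid (AABB) carries two chromosome sets from each
of two diploid progenitor species. Its meiosis is not yet fully
diploidized: occasionally a chromosome pairs and recombines with its
homoeolog from the other subgenome instead of its homolog. Such
homoeologous exchanges, followed by drift to fixation under self-pollination,
convert stretches of the genome from the balanced AABB configuration to
AAAA or BBBB — the genome gradually rearranges itself, and the process is
cumulative ("polyploid ratchet"). `polyhe` quantifies this process from
SNP-array genotype calls of selfing lineages and provides a forward
simulator of the same process for validation and power exploration.

## From chip calls to genome configurations

The readout is built on *parental-diagnostic loci*: SNPs at which the two
diploid parents are homozygous for different alleles. In a tetraploid, the
chip call at such a locus reflects subgenome dosage, but only coarsely. A
heterozygous call is compatible with 2:2, 3:1 and 1:3 dosage alike; only
the two fixed states are unambiguous:

| call (oriented) | configuration |
|---|---|
| heterozygous | AABB (any mixed dosage) |
| homozygous for the A-parent allele | AAAA |
| homozygous for the B-parent allele | BBBB |
| no call | unresolved |

Two consequences shape everything downstream. First, the readout is
*dosage-blind*: a reciprocal (balanced) exchange that leaves 2:2 dosage is
invisible, so every detected rate is a lower bound on the true amount of
ancestry rearrangement. Second, unresolved loci carry no configuration
evidence and are excluded from every denominator.

Quality control before classification follows standard array practice, in
a fixed order: per-sample call rate (retain strictly above 0.90), discard
of markers with conflicting technical-replicate calls followed by collapse
of replicates to one consensus column per plant, per-marker missingness
(remove strictly above 0.20), minor-allele frequency over the tetraploid
cohort (retain strictly above 0.05), then diagnostic selection and
per-locus orientation of calls to the parents. Replicates are collapsed
*before* the per-marker statistics so a plant genotyped twice is not
counted twice; MAF uses tetraploids only because the two fixed parents
would otherwise pull every frequency toward 0.5. A replicate pair with one
missing call is treated as consistent (missingness is non-informative) and
the consensus takes the non-missing value. All thresholds sit in
`filter_config()` and are echoed into the filter report; the diagnostic
count is reported both before and after the MAF stage, since the two
conventions are both in circulation.

## Blocks and interspersed loci

Converted loci come in two spatial patterns with different mechanistic
interpretations: runs of adjacent converted loci (*blocks*, the footprint
of a homoeologous crossover plus fixation) and isolated converted loci
(*interspersed*, attributed to gene conversion). The partition rule in
`segment_pair()` is deliberately simple and fully deterministic: maximal
runs of one converted configuration, tolerating at most `max_gap_loci`
(default 1) consecutive unresolved loci inside a run; a balanced AABB
locus always terminates a run, because a block is defined by contiguous
converted dosage. Runs with at least `min_block_loci` (default 3)
converted loci are blocks; the rest are reported locus by locus.

The default of 3 is a judgement call — the qualitative distinction between
"continuous segments" and scattered loci carries no universal numeric
threshold — chosen as the smallest run length unlikely to arise from
independent single-locus conversions at the conversion densities this kind
of data shows. Both knobs are exposed in `segmentation_config()` and echoed
in output headers, and any count of blocks should be read as conditional
on them. No HMM or changepoint machinery is used: at array marker density
the signal is essentially noiseless runs, and a scan that an auditor can
re-derive by eye is worth more than model flexibility. Ties cannot occur:
a converted locus that could join two gap-separated runs joins the earlier
one, a consequence of the single left-to-right pass. The segmentation is
cross-checked in the test suite against an independent regular-expression
run enumerator on tens of thousands of random sequences.

## Rates, bias, collapse, trend

`summarize_samples()` computes, per sample, the detected exchange rate
`he_rate_pct = 100·(n_AAAA + n_BBBB)/n_classified` and its direction
components; the decomposition `he = aaaa + bbbb` holds exactly (the total
is computed as the sum). Cohort summaries report both the pooled-loci rate
and the mean of per-sample rates, because both conventions are common and
they differ when sample sizes differ. The per-chromosome distribution is
given two ways: each pair's *share* of all conversions (sums to 100%) and
each pair's *within-pair* rate; printed per-chromosome percentages in the
literature are usually shares, but emitting both lets either reading be
checked. `conversion_bias()` labels per-sample asymmetry as balanced within
a configurable band around 50% (default ±5 percentage points).
`detect_total_collapse()` flags sample × pair combinations whose classified
loci are entirely AAAA (or entirely BBBB) — the end state of the ratchet on
one chromosome pair.

The generational trend is tested without distributional assumptions:
Spearman rank correlation of rate against selfing generation, a Theil–Sen
slope in percentage points per generation, and a one-sided permutation
p-value (labels permuted, default 10,000 permutations, seeded). A
rank-based choice is deliberate: per-sample rates are small proportions
with strongly unequal variances across generations, and the scientific
claim at stake is monotone accumulation, not linearity. A constant series
returns rho 0 and p 1 by convention.

## The forward simulator

`sim_config()` + `simulate_lineage()` implement a mechanistic null model of
one selfing lineage, used both to generate pipeline inputs with the exact
structure the analysis assumes and to provide ground truth for parameter
recovery. Per homoeologous chromosome pair the state is four haplotypes
(two per subgenome slot), each an origin vector over the marker loci.
Each generation, two gametes are drawn from independent meioses:

* with probability `p_he` per pair per meiosis, one homoeologous crossover
  between a randomly chosen A-slot and B-slot chromosome, at a relative
  position drawn from a Beta(1/b, 1/b) density — the symmetric U-shaped
  law with weight ∝ [u(1−u)]^(1/b−1); `b = 1` is uniform and the default
  `b = 4` concentrates breakpoints near the chromosome ends, where
  homoeologous pairing and crossing-over are concentrated in
  allopolyploids;
* gene conversion copies the ancestry of a `gc_tract_loci`-long tract
  (default 1 locus) from a random homoeolog at rate `p_gc` per locus per
  meiosis;
* a gamete takes one chromosome from each slot; selfing joins two gametes.

Crossovers exchange material, so per-locus dosage summed over the four
haplotypes is conserved within the meiotic cell; conversion copies and is
the only non-conserving event. Fixation arises purely from random gamete
sampling under selfing — no fitness, no aneuploidy, no lineage loss. The
readout maps dosage 4/0 to homozygous calls and everything else to
heterozygous (the same dosage-blindness as the chip), then applies
per-call genotyping error (flip to a uniformly chosen other state,
`error_rate`, default 0.002) and dropout (`missing_rate`, default 0.02).
Every event is logged, and per-generation dosage and ancestry-altered
flags let any detected quantity be compared against truth.
`emit_cohort()` writes a complete input set — including two synthetic
parent columns and noisy technical replicates per plant — so the entire
QC-to-trend pipeline can run end-to-end on simulated data.

Default study conditions: 10 chromosome pairs × 400 equally spaced loci
(about 4,000 diagnostic loci, emulating a ~4,263-locus array panel on
~150 Mb pseudomolecules), 8 selfing generations, `p_he = 0.05`,
`p_gc = 1e-4`. The exchange and conversion rates are *illustrative, not
estimated*: the true per-meiosis homoeologous crossover rate in such
material is unknown, and these values were chosen once so that detected
rates across generations land in the 1–20% range reported for real
neoallotetraploid lineages. Equal marker spacing is the default because it
makes segment geometry analytically checkable; uniform random spacing is a
switch. All randomness derives from a single seed, split per lineage by a
counter, so enlarging a cohort never perturbs existing lineages and every
run is bit-reproducible.

### What the simulator does and does not emulate

It reproduces the *structure* of real data — diagnostic-locus geometry,
dosage-blind calls, error, missingness, replicates, selfing pedigrees,
block versus interspersed footprints, generational accumulation and its
between-lineage variance, total collapse as an absorbing state, and the
invisible balanced fraction. It does not emulate: exchanges already
present at the polyploidization event itself (the simulated S0 is
perfectly balanced, so simulated early generations show fewer detected
conversions than real early-generation material, where instability begins
before the first selfing); direction bias between AAAA and BBBB (the model
is symmetric; real material can favor one subgenome); aneuploidy and
lineage mortality; and locus-specific error structure. Passing tests
therefore validate the pipeline's arithmetic and the detection logic, not
any organism-specific rate.

One geometric subtlety is worth recording: because a simulated crossover
exchanges everything distal to its breakpoint, blocks are end-anchored,
and a breakpoint very near one end produces a near-whole-chromosome block
whose *midpoint* is central. Midpoint-based distality statistics
(`distal_enrichment()`) therefore separate biased from uniform breakpoint
laws, but need not rank blocks as more distal than uniformly scattered
interspersed loci under every parameterization. In real data, where
exchanged tracts are typically short and terminal, the midpoint statistic
behaves as intuition suggests.

## Numerical and testing choices

Rates are computed from integer counts and only rounded (to 2 decimals,
matching common reporting precision) at the output-writing boundary.
Threshold boundaries are strict as documented above and config-exposed.
Degenerate inputs are flagged rather than silently dropped: zero
classified loci, zero conversions and block-free segment sets yield `NA`
statistics with a flag column.

The validation suite runs at these problem sizes: segmentation equivalence
on 10,000 random sequences (length ≤ 50); the null model (no exchange, no
conversion, no error) over 100 seeds, which must give exactly 0.00%
detected; parameter recovery with 200 simulated lineages at `p_he = 0.2`
over 8 generations against an independent coarse dosage-chain Monte-Carlo
oracle (the oracle tracks only per-locus origin bits through crossover,
conversion and selfing, with no breakpoint or event machinery, and its
95% interval uses the combined two-sample standard error); event-type
recovery (conversion-only simulations must classify ≥95% of converted
loci interspersed, crossover-only ≥95% in blocks, on clean data);
systematic underestimation (detected rate never above the truth
ancestry-altered fraction, 100 seeds, clean readout — genotyping error is
excluded there because a mis-call is not an exchange and can dominate when
the truth is near zero); and the ratchet (median Spearman rho over 100
simulated multi-generation cohorts strictly positive).

## Known limitations

Detected rates are lower bounds (balanced exchanges invisible; 3:1 dosage
invisible). Block counts are threshold-conditional. The trend test treats
lineages as independent, which technical replicates (collapsed) and shared
pedigrees may violate in other designs. The pipeline consumes genotype
calls; it neither re-clusters probe intensities nor calls intermediate
dosage classes from signal, and it does not model or detect aneuploidy,
which cytogenetics handles better.
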