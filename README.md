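# polyhe

Genome-wide detection and simulation of **homoeologous exchange (HE)** in
induced allotetraploids from SNP-array genotype calls.

## The scientific problem

A newly formed allotetraploid (genome AABB, one diploid chromosome set
doubled from each of two progenitor species) is genomically unstable:
chromosomes occasionally pair and recombine with their *homoeologs* from
the other subgenome. Combined with drift to fixation under selfing, these
exchanges convert regions of the genome from the balanced AABB
configuration to AAAA or BBBB, and the damage accumulates over generations
(the "polyploid ratchet"). `polyhe` is for researchers genotyping selfing
neoallotetraploid lineages (peanut-type AABB material and similar) on SNP
arrays who want to quantify this process.

At *parental-diagnostic loci* — SNPs where the two diploid parents are
homozygous for different alleles — a tetraploid's chip call reveals
subgenome dosage coarsely: HET ⇒ AABB (any mixed dosage), HOM for the
A-parent allele ⇒ AAAA, HOM for the B-parent allele ⇒ BBBB. The per-sample
detected exchange rate is

    he_rate% = 100 · (n_AAAA + n_BBBB) / n_classified ,

a **lower bound**, since balanced (reciprocal) exchanges and 3:1 dosage are
invisible to chip calls. The pipeline covers:

* **I/O** — genotype tables (Axiom-letter or numeric dialects), marker maps
  ordered on the B-subgenome pseudomolecules, sample metadata, optional VCF;
* **QC** — sample call rate (>0.90), replicate-consistency discard and
  replicate collapse, marker missingness (≤0.20), tetraploid-cohort MAF
  (>0.05), diagnostic-locus selection and parental orientation;
* **classification** — per-locus AABB/AAAA/BBBB/unresolved configurations;
* **segmentation** — maximal runs of converted loci into crossover-style
  *blocks* (≥3 converted loci, ≤1 unresolved gap, configurable) versus
  isolated *interspersed* conversions, plus distal-placement statistics;
* **statistics** — per-sample and cohort rates, AAAA/BBBB bias and
  asymmetry labels, per-chromosome shares, total-collapse flags, and a
  generational trend test (Spearman rho + Theil–Sen slope + one-sided
  permutation p);
* **simulation** — a forward model of a selfing AABB lineage (rare
  homoeologous crossovers with distally biased breakpoints, gene-conversion
  tracts, fixation by random gamete sampling, dosage-blind readout with
  error and missingness) with a complete truth log for validation.

## Worked example

Simulate a small cohort (8 lineages sampled at generations S2–S8), write it
to disk in the pipeline's file dialects, and run the full analysis:

```r
library(polyhe)
library(dplyr)

cfg <- sim_config(n_lineages = 8, n_generations = 8, seed = 2024)
files <- emit_cohort(cfg, "sim_demo", generations = rep(c(2, 4, 6, 8), each = 2),
                     event = "Demo")

qc <- run_qc(read_genotype_table(files$genotypes),
             read_marker_map(files$markers),
             read_sample_metadata(files$samples))
qc$report
#>   stage                 removed retained
#> 1 sample_call_rate            0     4000
#> 2 replicate_consistency     136     3864
#> 3 marker_missingness          0     3864
#> 4 maf                         0     3864
#> 5 diagnostic_selection        2     3862

config <- classify_configurations(qc$calls, qc$samples)
summarize_cohort(config, qc$markers, event = "Demo")
#> Homoeologous-exchange cohort summary [Demo]
#>   samples: 8   classified loci (pooled): 30883
#>   pooled rate: 6.65%  (AAAA 5.94% / BBBB 0.72%)
#>   per-sample rate: mean 6.65%, range 0.03%..21.75%

count(segment_all(config, qc$markers), kind, config)
#>   kind         config     n
#> 1 BLOCK        AAAA       7
#> 2 BLOCK        BBBB       2
#> 3 INTERSPERSED AAAA       5
#> 4 INTERSPERSED BBBB       5

summarize_samples(config) %>%
  inner_join(qc$samples[c("sample_id", "generation")], by = "sample_id") %>%
  generation_trend(n_perm = 10000, seed = 1)
#> Generational trend of homoeologous exchange
#>   n = 8 samples; Spearman rho = 0.781; Theil-Sen slope = 2.955 %/generation
#>   one-sided permutation p = 0.0173 (10000 permutations, seed 1)
```

Reading the output: of ~4,000 simulated diagnostic loci, 136 markers are
discarded because technical replicates disagreed (genotyping error), and 2
because an error corrupted a parental call. Across the 8 plants, 6.65% of
classified locus calls are converted, with a strong excess of AAAA in this
run; 9 conversion events are contiguous blocks (crossover footprints) and
10 are isolated loci (gene-conversion footprints); the detected rate rises
by ~3 percentage points per selfing generation, a monotone accumulation
(rho = 0.78) unlikely under shuffled generation labels (p = 0.017).

`plot_chromosome_paint(config, qc$markers, segments = ...)` draws the
per-chromosome mosaic of configurations, and `autoplot()` on the trend
object plots rate against generation with the fitted Theil–Sen line.

A thin command-line wrapper (`inst/cli/polyhe`) exposes the same stages as
subcommands (`simulate`, `qc`, `classify`, `segment`, `summarize`, `trend`,
`paint`), each writing a `manifest.json` with input/output digests so runs
are byte-reproducible.

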