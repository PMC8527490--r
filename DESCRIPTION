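Package: polyhe
Title: Detection and Simulation of Homoeologous Exchange in Neoallotetraploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of homoeologous exchange in induced
    allotetraploids from SNP-array genotype calls. Reads genotype-call
    matrices, marker maps and sample metadata; applies marker and sample
    quality-control filters and selects parental-diagnostic loci; classifies
    per-locus subgenome dosage into AABB/AAAA/BBBB configurations; segments
    chromosomes into exchange blocks and interspersed gene-conversion loci;
    and computes exchange rates, subgenome bias, total-collapse flags and
    generational accumulation trends. Includes a forward simulator of a
    selfing neoallotetraploid lineage (homoeologous crossovers with distal
    bias, gene-conversion tracts, drift to fixation under selfing, and a
    chip-like dosage-blind readout with error and missingness) with a
    complete truth log for validation, plus chromosome-paint plots and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
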