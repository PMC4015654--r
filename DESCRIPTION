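Package: cescan
Title: Compression-Efficiency Analysis of SNP Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes compression efficiency (CE) of serialized SNP genotype
    strings as a proxy for genome compositional regularity. Provides
    per-individual genome-wide CE versus heterozygosity for population
    discrimination, a heterozygosity-corrected sliding-window scan (CEhZ)
    that prioritizes genomic regions of shared population-level composition
    (including selection signatures), permutation and population-proportion
    randomization null models that bound the attainable information space,
    a RAND2 noise-floor curve across the full heterozygosity range, and a
    mosaic-of-founders genotype simulator with planted shared-haplotype
    regions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
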