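---
title: "Compression efficiency as a population-genomic statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression efficiency as a population-genomic statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cescan)
```

## The statistic

A diploid biallelic genotype profile is a string over `{0, 1, 2, 9}`
(homozygous wildtype, heterozygous, homozygous variant, missing). Two
numerical properties carry population-genetic information: the
*proportion* of each symbol (heterozygosity, homozygote bias) and their
*order* (haplotype blocks, runs of homozygosity, LD). A lossless
compressor exploits both simultaneously, so the compression efficiency
of the serialized profile,

$$\mathrm{CE} = \frac{S_B - S_A}{S_B},$$

with $S_B$ and $S_A$ the byte sizes before and after compression, is a
single number summarising the total compositional regularity of a
genome. Shannon entropy of the symbol proportions captures only the
proportion axis; CE additionally captures order, which is where most of
the population-shared signal lives. DEFLATE (LZ77 matching within a
32 kb window plus Huffman coding) is the compressor throughout; it is a
practical, fast proxy for the uncomputable Kolmogorov complexity.

Two serializations are used and must be byte-exact for results to be
reproducible:

* **individual column** — one code character plus one newline per locus,
  genome order (autosomes in natural order, then X; ascending position
  within chromosome): $2 n_{\text{loci}}$ bytes;
* **population matrix** — one newline-terminated row of code characters
  per sample over a window of loci:
  $n_{\text{samples}} (n_{\text{loci}} + 1)$ bytes.

Missing codes stay in the payload (they are part of the string being
described) but are excluded from heterozygosity, which is a
genotype-call statistic: $\%Het = 100\, n_1 / (n_0 + n_1 + n_2)$.

## Fixed-header gzip members and the exemplar calibration

The command-line gzip tool stores the input filename and timestamp in
its member header, which would make $S_A$ — and hence CE — depend on
what a file happened to be called. `compressed_size()` therefore builds
a fixed member: a 10-byte header (no name, zero mtime), an optional
fixed metadata allowance, the raw DEFLATE stream, and the 8-byte
CRC/length trailer. CE becomes a pure function of content for a given
zlib build.

The seven published 30-SNP exemplar strings
(`exemplar_strings()`) anchor the absolute scale. Their printed CE
percentages imply compressed sizes that exceed a no-metadata gzip
member at every DEFLATE level by 5–7 bytes, varying by row — the
signature of per-file filename metadata of differing lengths in the
original computation. No single fixed setting can therefore reproduce
all seven byte-for-byte. `calibrate_profile()` resolves this as a joint
sweep: candidate (level, memLevel, metadata allowance) settings are
scored against all seven printed values as a unit and the setting with
the smallest worst-case deviation wins (level 7, memLevel 1, 7-byte
allowance on this zlib build: the three single-individual rows exact,
the four matrix rows within 1.3 percentage points, ordering preserved).
Percentages are *truncated*, not rounded, to two decimals at reporting
boundaries (7/60 → 11.66); internally CE is always a fraction, so no
double-truncation can occur.

The calibrated profile matters only when comparing against the
published exemplar numbers. Every relative analysis — window z-scores,
population contrasts, null-model gaps — is invariant to the constant
allowance and insensitive to the level, and uses the plain default
profile (level 6, no allowance).

## The CEhZ window scan

For each population, windows of `window` (default 50) consecutive SNPs
slide one SNP at a time, never crossing a chromosome boundary. Each
window's population matrix is compressed; the window statistic is

$$\mathrm{CEh} = \frac{\mathrm{CE}\,(\%)}{\%Het},$$

which removes the first-order dependence of CE on heterozygosity so
that what remains is predominantly *order* shared across the
population. CEh values are z-normalized genome-wide — the X chromosome
as its own stratum, because its hemizygosity-driven homozygosity would
otherwise shift the genome-wide mean — using the sample ($n-1$)
standard deviation (a fixed, manifest-recorded convention). Each SNP
receives CEhZ, the mean z of all windows covering it (50 for interior
SNPs, fewer at termini). SNPs with CEhZ at or above the threshold
(default 3 standardized units) are single-link clustered with a 20 kb
gap and exported as 0-based half-open BED regions.

Numerical choices: windows whose %Het is zero have undefined CEh
(division by zero) and are excluded from normalization and per-SNP
averaging, with a logged count; SNPs covered only by such windows carry
`NA`. A zero-variance stratum is an error rather than silent z = 0. The
published threshold phrase "3-fold higher than the average" is
degenerate after normalization (the mean is ≈ 0 by construction), so
both readings are implemented: `z3` (≥ 3 z-units, default) and
`mean3x` (≥ 3 × per-chromosome mean CEhZ) — the mode is recorded in the
run manifest.

## Null models and the information-space boundary

* **RAND1** permutes an individual's code multiset: proportions kept,
  order (and hence LD) destroyed. Real CE above the RAND1 mean measures
  order-driven regularity.
* **RAND2** draws i.i.d. codes with the individual's heterozygosity but
  the *population's* homozygote split: $P(1) = h$,
  $P(0) = (1-h)\rho$, $P(2) = (1-h)(1-\rho)$. (A 3:1 population
  homozygote ratio at 20% heterozygosity gives 60/20/20.) I.i.d. rather
  than exact-count draws keep the noise floor well defined; an
  `exact = TRUE` mode provides multiset parity with RAND1. RAND2 never
  emits missing codes.
* **Sorted bound**: sorting the multiset ascending is the most
  compressible arrangement — the upper boundary of attainable CE for a
  given composition.

Sweeping RAND2 over $h \in [0, 1]$ with an even split $\rho = 0.5$ (the
maximally entropic choice, used for the outer boundary) gives the
noise-floor curve: the minimum attainable regularity at each
heterozygosity. Its minimum sits at $h = 1/3$, where the three-symbol
source is uniform and most entropic; at $h = 1$ the string is constant
and at $h = 0$ it is two-symbol noise, which still compresses better
than three-symbol noise. The curve is estimated on a 1% grid with 10
replicates of 50,000 genotypes per point (about 15 s); the acceptance
band for the argmin, 30–37%, reflects replicate noise at that size.

## The simulator and what passing tests mean

`simulate_panel()` builds diploid genotypes by pairing two haplotypes
per sample, each a mosaic of the population's founder haplotypes
(switching founders with probability `recomb_prob` per inter-SNP
interval). This gives controllable LD with transparent ground truth at
desk scale — it is deliberately not a coalescent simulator and makes no
claim of demographic realism (no migration, growth or admixture).
Ancestral frequencies are Beta(1, 1) by default (expected
heterozygosity ≈ 33%, matching the entropic centre of the noise-floor
curve); populations diverge by independent Wright–Fisher binomial drift
(`drift_generations`, `effective_size`). Planted `shared_haplotype`
regions overwrite a chosen span in a `sharing_fraction` of samples with
one fixed founder pair differing at ~30% of region loci, so the planted
pattern is compositionally complex (in-region heterozygosity ~30%,
nothing like an ROH); `roh` mode plants homozygous stretches for
contrast. Same spec + seed is byte-identical.

Validation experiments use these frozen conditions:

* **Peak recovery**: 30 samples, one 2,500-SNP chromosome, one planted
  100-SNP fully shared haplotype (sharing fraction 1). The planted span
  is ~4% of the genome — large enough to measure, small enough not to
  distort the genome-wide normalization (a planted region spanning a
  large fraction of all windows would cap attainable z-scores). The
  top-ranked peak overlaps the truth in ≥ 90% of 50 seeded replicates.
* **Order/LD ordering**: 2 founder haplotypes, switch probability
  0.001, 5,000 loci. Payload length matters here: DEFLATE sizes are
  quantized in whole bytes, so on short sequences a real-vs-permuted CE
  gap of a few parts per thousand can vanish into quantization noise;
  from ~5,000 loci the ordering CE(sorted) ≥ CE(real) > mean CE(RAND1)
  is stable for every individual.
* **F_ST concordance**: four populations drifted 5/20/60/120
  generations at $N_e = 100$ from one ancestral pool, 20 samples each,
  600 loci; Pearson r(|ΔCE|, F_ST) is positive in every one of 20
  seeded replicates (mean r ≈ 0.7). The F_ST reference is the Hudson
  estimator (ratio of averages, genome value clamped at 0); in real
  analyses the F_ST table is user-supplied.

What these panels do *not* emulate: SNP ascertainment bias, variable
marker density, genotyping error, population stratification within
labels, and sequence-level mutation processes. Passing tests
demonstrate that the implementation detects the compositional
structures the method is designed for — not that those structures are
the only explanation of peaks in real data, where the usual caveats of
selection-scan interpretation apply.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window` | 50 SNPs | scan resolution; sensitivity varies by region and should be tuned case by case |
| `threshold` / `threshold_mode` | 3 / `z3` | peak detection cutoff in z-units (or ×mean with `mean3x`) |
| `cluster_gap_bp` | 20,000 | max within-peak gap between selected SNPs |
| `replicates` | 10 | null-model averaging depth |
| `homo_ratio` | population-observed (RAND2); 0.5 (noise floor) | homozygote split of the null |
| compressor profile | level 6, no allowance | calibrated profile only for exemplar comparison |

## Known limitations

CE depends on the zlib build; absolute values are comparable only
within one build (the run manifest records the version). Byte
quantization limits resolution on short payloads — single windows are
meaningful only relative to the genome-wide distribution, never in
isolation. Hemizygous male X genotypes are accepted exactly as coded in
the input (no recoding), so X-stratum results inherit the upstream
calling convention. The scan assumes dense, ordered markers; very
sparse chromosomes (< 1 window) are skipped. Like other haplotype-style
scans, CEhZ does not model population stratification within a labelled
population.
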