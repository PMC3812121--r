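---
title: "Methods: fine-mapping from pooled sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-mapping from pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolfinemap)
```

## The measurement model

Pooled sequencing combines the DNA of all individuals in an arm into one
(or a few) libraries. What it measures, per variant and per pool, is an
allele-frequency estimate subject to three layers of error:

1. **Binomial sampling** of `2N` chromosomes from the population;
2. **assay estimation error**, everything between the library and the
   reported frequency (amplification imbalance, alignment, base calling),
   summarised by a single per-arm variance `s_e` in squared-frequency
   units, measured as the mean squared error of pooled estimates against
   genotype-derived frequencies on variants assayed both ways
   (`estimate_estimation_error()`);
3. **grid quantisation**: a pool of `2N` chromosomes can only hold
   frequencies that are multiples of `1/2N`, so estimates are rounded to
   that grid (`round_allele_frequency()`).

Everything downstream is built on this model. The per-variant test
(`modified_two_proportion_z()`) is the pooled two-proportion Z-test with
`s_e,case + s_e,control` added to the sampling variance; with both terms
zero it reduces exactly to the textbook statistic, which the test suite
asserts to 1e-12.

### Why `s_e` is a variance, added once per arm

`s_e` is defined as a mean squared error, i.e. already on the variance
scale, and is treated as homoscedastic across sites and independent of
sampling. Only this reading reproduces the published operating behaviour
of the test: at case/control frequencies 0.502/0.512 with 254/270 alleles
and `s_e` = 0.00081/0.00032, the total standard deviation is 0.055 and
the two-sided P is 0.86, where the sampling-only test would give a
noticeably smaller P. The homoscedasticity assumption is the weakest
part of the model for rare variants, whose relative error is then large;
we keep it because nothing in the calibration data identifies a
frequency-dependent error profile.

## Tunable parameters and their defaults

| parameter | default | units | role |
|---|---|---|---|
| `maf_cutoff` (scan) | 0.05 | frequency | common-variant definition, strict `>` on the allele-count-weighted pooled MAF |
| `maf_cutoff` (burden) | 0.01 | frequency | rare-variant definition, strict `<` in **both** arms |
| `r2_cutoff` | 0.9 | — | tag-SNP selection, strict `>` |
| `freq_cutoff` | 0.05 | frequency | major-haplotype boundary, ties kept as major |
| `coverage threshold` | 30 | reads/site/allele | detection-power saturation point; sites strictly below are flagged |
| `se_case`, `se_control` | 8.1e-4, 3.2e-4 | frequency² | per-arm estimation-error variances |
| `conservation alpha` | 0.05 | probability | conserved-site flag, strict `<` |
| `min_len`, `max_gap` | 50, 200 | bp | conserved-element candidate-region rules, both strict |

Boundary semantics were chosen once and are tested: rounding ties go away
from zero (the larger allele count), a haplotype group at exactly 5% of
chromosomes is major, a conservation P of exactly 0.05 is *not*
conserved, and a variant whose P equals the weakest tag's is *not*
"stronger than the tags".

## The scan threshold

The common-variant scan (`scan_common_variants()`) ranks variants by the
modified Z-test and compares each against the *least significant* of the
designated tag SNPs — the logic being that a causal variant should
associate at least as strongly as the markers that discovered the locus.
The comparison is strict; a variant tied with the weakest tag does not
count. The count of stronger variants includes any tag that is itself
stronger than the weakest tag; tags are flagged in the output so either
convention can be read off.

## Haplotype mapping

Chromosomes of a phased reference panel are grouped by exact allele-vector
identity over the interval (`cluster_major_haplotypes()`); no imputation
of partially observed chromosomes is attempted. Tags are sites whose
allele indicator has r² > 0.9 with group membership across panel
chromosomes; each tag records which allele marks the haplotype, and the
pool-level haplotype frequency is the arithmetic mean of the tag-oriented
pool frequencies. The per-tag spread is reported but outliers are never
dropped automatically — exclusion is a caller's decision.

Pool data never show haplotypes directly, so the Fisher test reconstructs
counts as `round(freq × 2N)`. The odds ratio reported alongside the exact
P is the sample cross-product ratio with a log-normal Wald CI (the CI
method is a convention choice; nothing in the data selects one). The
conditional independence test removes all chromosomes of one haplotype
from both denominators and re-tests the other, collapsing to OR = 1 when
an apparent effect was only the mirror image of the excluded haplotype's.

Recombinant individuals are defined by discordant dosages within a tag
set: if a haplotype's tags are perfect proxies, an individual's dosages
at them must agree, so discordance certifies a chromosome carrying only
part of the tag-defined haplotype. This is a reconstruction of the
field-standard practice; with imperfect tags it can both miss recombinants
and flag genotyping errors, which is why the joint GLM is run after
excluding them.

## The synthetic-data module

The generators are first-class, tested code, and their defaults *are* the
study conditions:

- **panel**: 186 phased chromosomes × 39 common sites over 9 kb, four
  major haplotypes at frequencies 0.358, 0.195, 0.126, 0.091 (summing to
  0.77). The last two frequencies are the risk- and protective-haplotype
  frequencies of the motivating design; the first two are not separately
  determined anywhere, so the remaining 55.3% of major mass was split
  roughly 65/35 once and kept. Each major carries two planted private
  derived alleles: one strictly private (rare chromosomes never carry it,
  so a perfect r² = 1 tag is guaranteed to exist) and one "leaky" that
  spliced recombinants may carry partially — giving recombinant detection
  a realistic signal. Twenty additional rare sites hold singleton or
  doubleton alleles confined to rare chromosomes, feeding the burden
  analysis. Remaining chromosomes (23%) are point-mutated copies (60%)
  or two-template splices (40%) of majors.
- **cohort**: 127 cases and 135 controls drawn by rejection sampling from
  a logistic disease model, log-odds
  `logit(0.055) + d_risk·ln(1.89) + d_prot·ln(0.50)`; 0.055 is a
  realistic population prevalence for the motivating phenotype, and the
  intercept is a nuisance under retrospective sampling.
- **pools**: two pools per arm (76/24 within cases, 56/44 within
  controls — with the default cohort: 192, 62, 150, 120 alleles), each
  site receiving Gaussian noise with the arm's `s_e`, truncation to
  [0, 1], then grid rounding. Gaussian is a maximum-entropy choice: the
  error is only ever specified by its variance.
- **spike-ins**: 13 positive and 50 negative control scores; with
  positive separation the construction pins the positive minimum exactly
  `separation` units above the negative maximum, so calibration must
  discriminate with 100% accuracy.

What the generator does **not** emulate: read-level data (no FASTQ, no
alignment), frequency-dependent estimation error, population structure,
genotyping error in the validation table, and linkage to anything outside
the simulated interval. Passing tests therefore certify the statistical
chain under its own assumptions, not the upstream bioinformatics.

## Numerical choices and degenerate inputs

- A pooled frequency of exactly 0 or 1 with zero estimation error has no
  testable variance and raises an error rather than returning P = NaN.
- Overlapping spike-in score distributions yield `separable = FALSE`
  instead of a guessed cutpoint.
- Zero-margin haplotype tables return P = 1 with the odds ratio flagged
  undefined; cross-product ORs with empty cells are 0/`Inf`/`NA`
  according to which margin is empty.
- (Quasi-)separation in the joint GLM is detected from exploding
  coefficients or fitted probabilities at machine 0/1 and reported as a
  flag with no estimate.
- PWM "binding energy" is operationalised as the maximum additive window
  score over both strands; scanning-tool versions differ here, so
  percentage disruptions are comparable only within one matrix and
  scanner. Hit counting uses a threshold at 80% of the motif's maximum
  attainable score; motifs with more than 20 hits across the scanned
  interval are excluded as non-specific, and that exclusion dominates the
  equal-score exclusion.
- Intervals are BED-convention 0-based half-open; variant positions are
  VCF-convention 1-based; the conversion lives in one place
  (`regulatory_overlap()`).

## Problem sizes used in validation

The test suite regenerates all data at the default scale (186-chromosome
panel, 127/135 cohorts). Monte-Carlo checks use 10,000 replicates for the
type-I error of the modified Z-test (band 0.05 ± 3·MC-SE), 200 cohort
replicates for Wald CI coverage of the generating odds ratios (≥ 93%
coverage expected at nominal 95%), 200 replicates for mean log-OR
recovery, and 1,000 sites for `s_e` recovery. The acceptance script's
GLM recovery uses 20,000 individuals per arm, which puts the Monte-Carlo
standard error of the fitted log odds ratios near 0.025. All bounds were
fixed from the model before running.

## Known limitations

- Arm-level aggregation of multi-pool estimates shrinks the effective
  estimation-error variance by the squared pool weights; the calibration
  stage estimates the arm-level variance directly from concordance data,
  so the scan stays calibrated, but per-pool and per-arm `s_e` values are
  not interchangeable.
- The burden test reconstructs integer carrier counts from frequencies;
  with very small collapsed frequencies the reconstruction is exact, but
  for frequencies near the grid midpoints it inherits the rounding rule.
- Tag-based haplotype frequencies assume LD measured in the reference
  panel transfers to the study cohorts (genetic homogeneity); nothing in
  the package can detect a violation.
- The homoscedastic Gaussian estimation error overstates noise for rare
  variants relative to a read-count model, making the synthetic burden
  analysis conservative.
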