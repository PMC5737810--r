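---
title: "Modelling somatic CpG mutation probability from methylation and replication timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling somatic CpG mutation probability from methylation and replication timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscape)
```

## The scientific problem

5-methylcytosine (5mC) deaminates spontaneously to thymine roughly fivefold
faster than unmethylated cytosine. At a CpG dinucleotide this produces a
G•T mismatch; if DNA replication outruns repair, the site is fixed as a C>T
mutation. Across a tumour genome, the per-CpG mutation probability is
therefore expected to rise with the methylation fraction of the site — but
how steeply, and whether monotonically, depends on the repair machinery
available to the tissue (mismatch repair for replication-coupled errors,
base-excision repair for deamination products, nucleotide-excision repair
in UV-exposed skin) and on replication timing, which modulates both
mutation supply and repair opportunity.

mutscape quantifies this with a single interpretable regression per cohort,
surrounded by the descriptive statistics needed to read it: binned
mutation-rate curves, slope contrasts between cohorts and timing strata,
spectrum-based sample classification, coding-hotspot enumeration and
origin-anchored strand-asymmetry tests.

## The model and its assumptions

For a cohort (or subtype) of samples, each autosomal CpG with methylation
data becomes one observation with

* `M` — methylation fraction in `[0, 1]`, taken from the cytosine of the
  forward-strand CpG of a tissue-matched normal WGBS track;
* `R` — replication timing of the enclosing 1 Mb window, averaged across
  cell-type tracks, higher = earlier;
* outcome — 1 if any sample of the cohort carries a deamination-class
  mutation on either base of the dinucleotide (C>T at the C or G>A at the
  G), else 0.

The binary logistic model is

$$\log\frac{P_{mut}}{1 - P_{mut}} = b_0 + b_1 M + b_2 M^2 + b_3 R + b_4 (M \times R).$$

Assumptions worth stating explicitly:

* **Independence across CpGs.** Sites are treated as independent Bernoulli
  draws; clustered mutational processes (kataegis, focal hypermutation)
  violate this and would narrow the reported standard errors.
* **Pooled binary outcome.** "Mutated in at least one sample" is the
  cohort-level outcome. Its link to the per-sample mutation law is not
  logistic (it is `1-(1-p)^S` for `S` samples), so cohort-level
  coefficients are attenuated summaries, not per-sample rates. Per-sample
  refits (`per_sample_slopes()`, `per_sample_vertices()`) avoid this.
* **Normal-tissue methylation.** The methylation covariate comes from
  normal tissue; tumour-specific methylation changes are not modelled
  (sample-matched bisulfite data cannot distinguish deamination-derived
  C>T from converted unmethylated C, so this is also a measurement
  constraint, not only a convenience).
* **Raw scales.** `M` enters uncentred on `[0,1]` and `R` on its native
  track scale, so coefficients are directly comparable across cohorts and
  the vertex is a methylation fraction.

The **vertex** `-(b1 + b4*R_ref)/(2*b2)` is reported at `R_ref` = the mean
timing of the fitted sites (the reference a reader most naturally wants;
any other reference can be passed to `model_vertex()`). Values outside
`[0,1]` are meaningful: a vertex above 1 means mutation risk increases over
the entire methylation range.

## Nested selection, AUC and the quadratic term

`select_model()` walks the chain intercept → `+M` → `+M²` → `+R` → `+M×R`.
Each step is tested with a likelihood-ratio test (`lmtest::lrtest`,
chi-square on the parameter-count difference) and the whole chain is also
ranked by AIC. The LRT choice is the largest model reached while every step
improves at p < 0.05; the AIC choice is the AIC minimum. When they
disagree, both are reported, `agreement` is set to `FALSE`, and the simpler
of the two is returned as `chosen` — a deliberately conservative tie-break.
The specification chain must be strictly nested; passing a duplicate
specification is an error rather than a degenerate zero-statistic step.

AUC is the Mann–Whitney probability that a random mutated site outscores a
random unmutated one, ties counted one half, computed in-sample (the model
is descriptive, not predictive; no held-out split). AUC gains from adding
timing (full vs `M+M²`) or methylation (full vs `R` only) are reported in
percentage points in `cohort_report()`.

## Binned associations

`binned_rate()` bins CpGs by methylation in widths of 0.1 (topmost bin
closed, `[0.9, 1.0]`), and computes per bin
`events / (CpG count × 2 bp) × 10⁶` — mutations per megabase of CpG
dinucleotide sequence, the 2 bp denominator making the rate a property of
the dinucleotide. Bin midpoints are the regression abscissae; empty bins
are excluded, and a fit is refused with fewer than three occupied bins.
Both pooled event counts (default) and mutated-site counts are supported,
since multi-hit sites make the two differ in hypermutated cohorts.

Slope contrasts (`compare_slopes()`) fit one OLS model to the stacked
binned points with a group-by-midpoint interaction against a chosen
reference cohort; the interaction t-tests are the reported slope-difference
p-values. Timing stratification (`stratify_by_timing()`) cuts the per-site
timing distribution at genome-wide tertiles — the highest tertile is
"early" — and bins each stratum independently; ties spanning a boundary are
assigned deterministically to the lower stratum with a warning. The
candidate-site contrast (`candidate_fraction()`) reports, per sample, the
percentage of low- (`M < 0.25`) and high- (`M > 0.75`) methylation TCG
sites carrying a C>T; both paired and unpaired t-tests are computed, with
the paired test as the headline (the two percentages are measured on the
same sample).

## Sample classification

A sample is POLE-mutant iff it has a somatic POLE mutation in the
exonuclease domain (amino acids 268–471, inclusive) *and* Pearson
correlation strictly above 0.85 between its 96-channel trinucleotide
spectrum and signature 10. Spectra are folded to the pyrimidine strand and
correlation is computed on proportion-normalized vectors (Pearson is
location/scale invariant, so this is presentational). An MSI-H annotation
takes effect only when the POLE rule fails; zero-variance spectra are
`unclassified` with a recorded reason. The shipped reference vector
(`inst/extdata/signature10_synthetic.tsv`) is a synthetic stand-in carrying
the hallmark channel dominance of signature 10 (T[C>A]T strongest, then
T[C>T]G); users with a published signature matrix should pass their own
file to `load_signature10()`.

## Hotspots and strand asymmetry

`enumerate_stop_gain_tcg()` scans an in-frame CDS on both strands for
single C>T events that lie in a 5'-TCG-3' context on the mutated strand
and convert a non-stop codon into an immediate stop (a template-strand
C>T is a coding-strand G>A in a CGA context). "Immediate truncation" means
the mutated codon itself becomes a stop — no readthrough or splice
reasoning. Edge contexts use explicitly supplied flanking bases; with the
default `N` flanks, edge candidates are skipped with a warning.

`strand_asymmetry()` classifies mutations of a pyrimidine-strand context
class within a flank (default 25 kb per side — replication-origin
asymmetry is a local leading/lagging effect and no canonical window exists)
of a declared origin by (5'/3' side) × (strand of the mutated pyrimidine)
and applies a two-sided Fisher exact test. `hotspot_contingency()` is the
matching 2×2 group-versus-mutated test for hotspot codons.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; the defaults are one
choice of a realistic desk-scale colorectal-like study and are not
revisited per analysis:

| Parameter | Default | Why |
|---|---|---|
| `genome_length`, `n_chrom` | 1 Mb × 2 | large enough for ~40k CpGs, seconds to simulate |
| `cpg_density` | 0.02 /bp | order of the human genome's CpG density |
| `meth_mix` | Beta(1.5,15) w=0.2; Beta(12,2) w=0.8 | bimodal landscape: hypomethylated island-like minority, methylated majority |
| `timing_range`, `timing_period` | 20–80, 250 kb | Repli-seq-like scale, smooth megadomain wave |
| `window_size` | 10 kb | scaled down from 1 Mb so a 1 Mb chromosome spans many windows |
| `coefficients` | (−8, 3, −1, 0.01, 0.005) | low per-site rates with positive, gently saturating methylation effect |
| `n_samples`, `sample_multiplier` | 10, 1 | modest cohort; multiplier models burden differences |
| `asym_ratio` | 0.9 | strong but not degenerate origin strand bias |

The generator emulates: a sequence with exactly controllable CpG content
(the background is built CpG-free, then CpGs are planted), bimodal
methylation, a smooth timing wave, per-sample Bernoulli mutations from the
logistic law (C>T at the C or G>A at the G with equal probability), toy
CDSs with known stop-gain TCG sites, signature-style T[C>A]T mutations for
POLE-like samples, and label-reassignment strand bias around declared
origins. It does **not** emulate: realistic k-mer composition, CpG
islands/promoter structure, clustered mutational processes, copy number,
tumour methylation drift, or more than one mutational signature per
sample. Passing tests therefore demonstrate statistical correctness of the
estimators under the stated generating law — not robustness to everything
real data contains.

Methylation is drawn independently of timing by default; the
`meth_timing_cor` knob introduces the confounding (methylated regions
replicating at characteristic times) that makes separating `b1/b2` from
`b3/b4` genuinely hard, for stress-testing.

## Numerical choices

* Logistic fits: `stats::glm`, binomial, deviance tolerance `1e-8`,
  maximum 100 iterations. Complete separation and single-class outcomes
  raise errors (naming the dominant term) rather than returning divergent
  coefficients.
* AUC is computed by midranks (exactly the tie-½ pairwise probability) and
  oriented to `[0.5, 1]`.
* One-sample t-tests with zero variance use the sign convention p = 1 when
  the common value equals the reference, p = 0 otherwise, flagged
  `degenerate`.
* Coordinates are 0-based half-open internally; BED-family input is read
  as 0-based, VCF-like input (including the mutation TSV's `pos`) as
  1-based and converted on read.
* When a CpG has only a G-strand WGBS record, that value is used as a
  logged fallback; CpGs absent from the track are dropped, not imputed.
  No minimum-coverage filter is applied by default; a threshold is
  exposed.
* Windows shorter than the nominal width at chromosome ends are kept and
  flagged; timing is averaged as usual. Non-autosomal contigs are excluded
  by a configurable allow-list.
* Every simulator stage seeds its RNG through a salted stream derived from
  the user seed, so identical seeds give identical outputs per stage while
  different stages (covariate draw vs outcome draw) never share a uniform
  stream — sharing one would correlate the outcome with the covariates
  outside the model.

## Problem sizes

The test suite and `scripts/acceptance.R` run at sizes chosen to make the
statistical checks sharp while staying interactive: 2×10⁵ CpGs for
coefficient and vertex recovery, 2×10⁵-site draws for vertex planting
(±0.05 recovery bands), 1,000 random CDSs against the all-substitutions
translation oracle, Fisher tables to n = 200 against full hypergeometric
enumeration, and 1,000 null replicates for the slope-comparison
type-I-error calibration (0.05 ± 0.02 acceptance band). The end-to-end
driver `reproduce_synthetic()` uses the default 2 × 1 Mb configuration.

## Known limitations

* The pooled cohort outcome attenuates coefficients relative to the
  per-sample law (see assumptions); cross-cohort comparisons should hold
  cohort size roughly constant or use per-sample refits.
* In-sample AUC mildly flatters model quality; differences between nested
  models are the intended reading, not absolute values.
* The signature-10 stand-in is synthetic; classification thresholds are
  meaningful only relative to the reference vector actually supplied.
* Gene models treat BED12 blocks as CDS exons and assume frame starts at
  the first block; UTR-aware inputs must be pre-trimmed.
* `read_timing` averages cell-type tracks equally; no weighting by track
  quality or coverage is attempted.
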