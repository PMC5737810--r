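# mutscape

Somatic C>T mutations accumulate preferentially at methylated CpG
dinucleotides, because 5-methylcytosine deaminates to thymine and the
resulting G•T mismatch is fixed as a mutation if the cell replicates before
repair. How strongly mutation load tracks methylation — and how that
association bends with DNA replication timing — differs sharply between
cancer subtypes: mismatch-repair-deficient (MSI) and POLE-exonuclease-mutant
colorectal tumours show much steeper methylation associations than
microsatellite-stable (MSS) ones, while in skin cancers nucleotide-excision
repair makes the association non-monotone.

mutscape is an R package for quantifying these effects. It is aimed at
cancer-genomics analysts who have whole-genome somatic mutation calls, a
tissue-matched WGBS methylation track and Repli-seq replication timing, and
want the complete path from raw tracks to a fitted mutation-probability
model — plus a synthetic-data generator so the entire pipeline can be
exercised and validated without any external downloads.

## The model

Each autosomal CpG is scored as mutated (in at least one sample of the
cohort) or never mutated, and a binary logistic regression is fitted:

```
log( P_mut / (1 - P_mut) ) = b0 + b1*M + b2*M^2 + b3*R + b4*(M x R)
```

where `M` is the methylation fraction of the CpG (from the cytosine of the
dinucleotide, in [0,1]) and `R` the replication timing of its enclosing
megabase window (higher = earlier). Nested models (intercept; +M; +M²; +R;
+M×R) are compared by likelihood-ratio tests and AIC; model quality is
summarized by the in-sample AUC. The **vertex** of the log-odds quadratic in
M at a reference timing,

```
M* = -(b1 + b4*R_ref) / (2*b2)
```

locates where increasing methylation stops increasing mutation risk; a
vertex above 1 means the association is monotone over the whole methylation
range.

Around the model sit the supporting analyses: binned mutation rate per Mb of
CpG sequence versus methylation (0.1-wide bins) with cohort slope
comparisons; replication-timing tertile stratification; per-sample slopes
and vertices; 96-channel trinucleotide spectra with MSS / MSI / POLE-mutant
classification (POLE exonuclease domain mutation at amino acids 268–471
*and* Pearson r > 0.85 with signature 10); exhaustive enumeration of C>T
stop-gain candidates at TCG trinucleotides in coding sequence; and Fisher
exact tests of mutation strand asymmetry across replication origins.

## Worked example

Simulate 50,000 CpGs with bimodal methylation and a smooth timing wave,
draw per-site outcomes from a known logistic law, and refit:

```r
library(mutscape)

cfg   <- simulation_config(seed = 7)
sites <- simulate_cpg_sites(5e4, cfg)
tab   <- simulate_outcomes(sites, c(-4, 3, -2, 0.01, 0.005), seed = 7)

fit_mutation_model(tab)
#> Logistic mutation-probability model: log(P/(1-P)) = -4.231 + 3.548*M + -2.402*M^2 + 0.01505*R + -0.0001385*M*R
#>   n = 50000 (4456 mutated)  logLik = -14617.55  AIC = 29245.09  AUC = 0.6261
#>   vertex = 0.737 at mean timing 50

binned_rate(tab)
#> Binned mutation-methylation association (events, 50000 CpGs)
#>   slope 4.072e+04  intercept 1.743e+04  r^2 0.596  p 0.00886

select_model(tab)
#> Nested logistic model selection
#>          step    df    statistic      p_value
#> 1:          M     1 349.05286173 6.813859e-78
#> 2:       M+M2     1  72.89566503 1.366881e-17
#> 3:     M+M2+R     1 392.66645155 2.174666e-87
#> 4: M+M2+R+MxR     1   0.00190317 9.652031e-01
#>   LRT choice: M+M2+R  AIC choice: M+M2+R
```

The recovered coefficients sit close to the generating ones (each within
two standard errors); the quadratic term and timing main effect are firmly
selected while the weak planted interaction (b4 = 0.005) is — correctly at
this sample size — not. The binned slope of ~4.1 × 10⁴ mutation events per
Mb of CpG sequence per unit methylation mirrors the positive
mutation–methylation association the model captures, and the vertex above
0.7 says risk still rises over most of the methylation range.

`reproduce_synthetic(seed, outdir)` runs the whole chain — genome
simulation, per-CpG annotation, sample classification, binned associations,
stratification, nested model selection, per-sample slopes, TCG stop-gain
scan, origin strand asymmetry — and writes per-stage TSVs plus a JSON
report with the exact configuration and seed.

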