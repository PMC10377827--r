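# mirct

Fold-regulation analysis of circulating miRNA qPCR-array Ct profiles.

## The problem

Serum microRNAs are promising minimally invasive biomarkers for dysglycemia:
expression shifts appear already in prediabetes (impaired fasting glucose,
IFG) and sharpen with overt type 2 diabetes (T2D). A common discovery design
profiles a few hundred miRNAs by real-time PCR on a 384-well array, pooling
equal RNA amounts per clinical group into a single profile, and calls
differential expression from signed fold regulation rather than replicated
statistics. `mirct` implements that entire workflow — from raw cycle-threshold
(Ct) tables to signatures — as tested, reusable R code, for analysts who work
with commercial serum/plasma miRNA PCR panels or want to evaluate such designs on
simulated cohorts with known truth.

## The model

For assay *m* in sample *s*, with reference statistic *R(s)*:

```
dCt(m, s)   = Ct(m, s) − R(s)
ddCt(m)     = dCt(m, test) − dCt(m, reference)
FC(m)       = 2^(−ddCt(m))                       (fold change, > 0)
FR(m)       = FC   if FC ≥ 1,  −1/FC otherwise   (signed fold regulation, |FR| ≥ 1)
```

Three interchangeable choices of *R(s)*: the **global Ct mean** (mean Ct of
all detected assays, endogenous controls and spike-in included — the
mean-centric method, most conservative), the mean Ct of **endogenous
controls** (snoRNAs/RNU6B), or the exogenous **spike-in** (cel-miR-39).
Detection requires Ct ≤ 35; a miRNA undetected in either group of a contrast
is *not evaluable*, never imputed.

On top of the per-contrast fold regulations sit three signature rules:
classification at |FR| ≥ 2 (up/down/unchanged), a **high-stringency** set at
|FR| ≥ 10 in any case-vs-control contrast, a **progression** set
(FR strictly increasing from the intermediate to the overt condition), and a
**condition-specific** set (regulated in one condition, quiet in the other).
Sample QC uses the hemolysis index Ct(miR-23a-3p) − Ct(miR-451a) (pass < 5
cycles), absorbance purity ranges, and expression tiers
(high Ct ≤ 25 / moderate ≤ 30 / low ≤ 35 / undetected).

## Worked example

Simulate a 3 × 10-sample cohort with twenty planted log2 effects (a
progression pattern: half-sized effects in IFG, full effects in T2D,
balanced up/down), then fit:

```r
library(mirct)
eff <- balanced_effects()                      # 10 up + 10 down, |e| in [1, 7]
sim <- simulate_cohort(recovery_sim_config(effects = eff), seed = 7)
fit <- mirct_fit(sim$ct, sim$panel, reference = "control")
fit
#> Fold-regulation analysis of qPCR Ct profiles
#>   normalization: global_mean; reference group: control
#>   372 target assays, 3 contrasts
#>   IFG_vs_control         up   8  down   8  unchanged 356  not evaluable   0
#>   T2D_vs_control         up   9  down   9  unchanged 354  not evaluable   0
#>   T2D_vs_IFG             up   8  down   9  unchanged 355  not evaluable   0
```

Under technical noise (sd 0.25 cycles) the fit recovers the planted
structure: all 18 miRNAs called up or down in the T2D-vs-control contrast
are planted ones (no false positives), only the two smallest plantings
(true FR exactly ±2) fall under the threshold after noise, and the
progression rule recovers 9 of the 10 up-planted miRNAs:

```r
summary(fit)$signature_sizes
#>    high_stringency        progression condition_specific
#>                 12                  9                 NA
head(coef(fit)[eff$mirna, ], 4)
#>              IFG_vs_control T2D_vs_control T2D_vs_IFG
#> sim-miR-0001       1.376462       1.913424   1.390102
#> sim-miR-0002       1.785535       3.395547   1.901697
#> sim-miR-0003       2.244237       4.592023   2.046139
#> sim-miR-0004       2.805452       7.425921   2.646961
```

The first planted miRNA (true FR 2 in T2D) lands just under the ±2 rule at
this noise level; the larger effects are recovered near their planted
magnitudes (true T2D-vs-control values for rows 2–4: 3.17, 5.04, 8).

The package also ships transcribed published fold-regulation tables for the
three dysglycemia contrasts; `run_pipeline(list(fixtures = "packaged"))`
classifies them and derives all signatures without any raw Ct input.

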