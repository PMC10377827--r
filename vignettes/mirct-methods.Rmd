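---
title: "Methods: from raw Ct values to fold-regulation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw Ct values to fold-regulation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirct)
```

## The measurement and the model

A real-time PCR array reports, per assay and sample, the cycle threshold
Ct — the PCR cycle at which fluorescence crosses detection. Ct is a
log2-scale measure of abundance with negative orientation: one cycle less
means twice the template. Reactions that never cross threshold come back
*undetermined*; `mirct` stores them as `NA` and additionally treats any
Ct above 35 as undetected, the conventional reliability limit for serum
miRNA arrays.

Relative quantification is the classic comparative-Ct chain. Per sample,
`dCt = Ct − R` with a reference statistic `R`; per contrast,
`ddCt = dCt(test) − dCt(reference)`; fold change `FC = 2^(−ddCt)`; and the
signed fold regulation `FR = FC` when `FC ≥ 1`, else `−1/FC`, so that
down-regulation reads as a negative magnitude and `|FR| ≥ 1` always. The
`FR` scale is convenient for reading tables but has a discontinuity — it
jumps from +1 to −1 as `FC` crosses 1 — so all internal exactness checks
are done on the continuous `log2(FC)` scale and `FR` is derived for
reporting.

Three reference statistics are supported and interchangeable:

* **global Ct mean** (`global_mean`, the default): `R` is the arithmetic
  mean of *all* detected assays in the sample, endogenous controls and
  spike-in included. This mean-centric choice assumes total measured
  expression is constant across samples at equal RNA input; it makes the
  per-sample `dCt` average exactly zero and is the most conservative of
  the three (it tends to shrink fold regulations, since any broad shift is
  absorbed into the reference). The mean is plain — no trimming — and is
  computed per sample over that sample's detected assays.
* **reference genes** (`reference_genes`): `R` is the mean Ct of the
  detected snoRNA/snRNA controls (SNORD61/68/72/95/96A, RNU6B). A subset
  of missing controls degrades gracefully with a warning; all-missing is
  an error.
* **spike-in** (`spike_in`): `R` is the Ct of exogenous cel-miR-39 added
  before extraction; it tracks recovery efficiency. An undetermined
  spike-in is treated as an extraction failure, not a data point.

All three are invariant to a constant per-sample Ct shift, which is the
mathematical content of "normalization": RNA-input and efficiency offsets
cancel in `dCt`.

### Missingness

`dCt` is defined only where the raw Ct is detected; nothing is imputed at
the detection limit. A miRNA undetected in either side of a contrast is
*not evaluable* and is excluded from signatures and counted separately —
imputing at Ct 35 would fabricate fold changes that the assay cannot
support.

## Pooling

The workflow mirrors a pooled design: equal RNA masses from all samples of
a group are combined and profiled once, so there is no within-group
replication and no per-miRNA hypothesis test — inference is by effect-size
thresholds. `pool_samples()` models the physical pooling on the linear
(copy-number) scale:

```
pooled Ct = −log2( mean over samples of 2^(−Ct) )
```

because mixing equal masses averages concentrations, not Ct values. The
pooled Ct of identical inputs is the identity, and always lies between the
per-sample extremes. Samples in which an assay is undetermined are
excluded from that assay's pool with a coverage flag; treating them as
zero concentration would let a single censored reaction dominate the pool
downward for no physical reason.

## Thresholds and signature rules

All thresholds are exposed as arguments with these defaults:

| parameter | default | units | role |
|---|---|---|---|
| `ct_max` | 35 | cycles | detection cut-off |
| `fr_threshold` | 2 | fold | up/down classification, condition-specific rule |
| `stringency_threshold` | 10 | fold | high-stringency signature |
| `hemolysis_threshold` | 5 | cycles | QC pass cut-off (strict `<`) |

Classification is inclusive (`FR ≥ 2` is up, `FR ≤ −2` is down) and is
evaluated at 2-decimal precision, because published tables print fold
regulations rounded to 2 decimals and list entries printed exactly at the
threshold among the regulated; reproducing printed counts requires
including them. Raising the threshold can only shrink the up/down sets
(monotonicity, covered by tests).

The **high-stringency** rule selects miRNAs with `|FR| ≥ 10` in at least
one case-vs-control contrast. The wording "low in one group and high in
the other" that motivates such cut-offs is ambiguous about which side the
cut applies to; we read it as a single arbitrary cut-off of 10 on the
contrast's fold regulation, the only reading consistent with plotting
signatures above an axis that starts at 10.

The **progression** rule is a predicate, not a curated list: a miRNA
qualifies when its fold regulation against the shared control increases
strictly from the intermediate to the overt condition and the overt value
is at least `min_fr`. On published tables the predicate is satisfied by
every member of the nine-miRNA progression signature reported in that
literature, but it selects more candidates than nine — whatever additional
criterion curated the printed list is not stated, so the package verifies
membership rather than pretending to reproduce the curation.

The **condition-specific** rule selects miRNAs regulated
(`|FR| ≥ threshold`) in the focal condition while the other condition is
quiet (`|FR| < threshold`, or absent), with a concordant direction when
the other condition shows any trend. Values for the quiet side may come
from narrative text rather than tables (printed tables usually list only
`|FR| ≥ 2` rows); the packaged fixtures therefore include a small separate
file of narrative sub-threshold values.

## Quality control

The hemolysis index is `Ct(miR-23a-3p) − Ct(miR-451a)`; erythrocytes are
rich in miR-451a, so lysis lowers its Ct and inflates the index. Pass is
strict (`index < 5` cycles); an uncomputable index (either Ct
undetermined) fails, since the contamination status is unknown. The index
is invariant to per-sample offsets, so it measures contamination, not RNA
input. Spectrophotometric purity ranges (A260/280 in [1.9, 2.1], A260/230
in [2.0, 2.2], inclusive) are optional metadata: a missing ratio is
reported unknown, not failed. QC failures flag samples without aborting
the pipeline unless `strict_qc = TRUE`, so contaminated synthetic samples
can be carried end-to-end in experiments.

Expression tiers over target assays (controls and spike-in excluded):
high `Ct ≤ 25`, moderate `(25, 30]`, low `(30, 35]`, undetected otherwise.
Upper edges are closed to match the conventional phrasing "Ct ≤ 25" /
"Ct ≤ 30"; the four tiers partition the panel.

## The synthetic cohort generator

`simulate_cohort()` generates
`Ct(m, s) = baseline(m) − effect[group(s)](m) + offset(s) + noise(m, s)`,
with reactions above a hard censor (40 cycles) returned undetermined. The
draw order is fixed (tier assignment and baselines, then per-sample
offsets, then reaction noise) so a seed fully determines the cohort.
Effects are planted as Ct *decreases* — higher expression, lower Ct — with
`e > 0` meaning up-regulation by `2^e`.

The default configuration emulates the study conditions of a three-group
serum profiling cohort: 10 samples per group (control/IFG/T2D), a
372-target panel with 6 endogenous controls and one spike-in, and a
baseline tier design placing 3 targets in the high tier and 35 in the
moderate tier of the control group, the remainder low or near the
detection limit — the profile reported for euglycemic serum. Per-sample
offsets default to sd 0.5 cycles (RNA input and extraction variability of
a careful column-based protocol) and technical noise to sd 0.25 cycles
(typical SYBR-array replicate scatter); neither value is given in the
study this emulates, so both were chosen once at these field-plausible
magnitudes. The hemolysis pair gets fixed clean-serum baselines
(miR-23a-3p 26.5, miR-451a 24.5, index 2), and contamination is injected
by lowering miR-451a by a configurable shift (default 6 cycles, i.e. a
clearly hemolyzed sample).

`recovery_sim_config()` is a documented variant for parameter-recovery
studies: every baseline is kept inside the detection window even after the
largest supported down-regulation (7 log2 units), so the detected assay
set is identical across groups. Together with a *balanced* planted-effect
table (`balanced_effects()`: effects summing to zero per group) this makes
the global-Ct-mean assumption hold exactly, and zero-noise recovery of
planted fold changes is exact to floating-point for every assay and
contrast. This is a deliberate test design: under the realistic default
tiers, assays near the detection limit drop out differentially and
mean-centric normalization is mildly biased whenever planted effects do
not cancel — which is precisely the known limitation of the mean-centric
method on strongly asymmetric signatures, not an artifact of this
implementation.

What the generator does **not** emulate: PCR efficiency differences
between assays, melt-curve artifacts, inter-plate calibration, carryover
between wells, and any dependence of censoring on amplification quality
rather than abundance. Passing recovery tests therefore demonstrates the
correctness of the analysis chain under the stated generative model, not
robustness to those instrument-level effects.

## Clinical covariates

Eligibility screening applies the exclusion criteria of a
confounder-free discovery cohort (CRP > 6 mg/L, ESR > 30 mm/h,
BMI > 30 kg/m², HbA1c > 8%, triglycerides > 175 mg/dL, smoking, alcohol or
drug use, eGFR < 60 mL/min/1.73 m², microalbuminuria); all are strict
inequalities, and a missing field reports the criterion unknown rather
than violated. Group summaries are medians with interquartile ranges
(quartiles by linear interpolation, `stats::quantile` type 7 — a
convention choice, documented so printed summaries are compared with
tolerance). Intergroup tests are Kruskal–Wallis via `stats::kruskal.test`
(tie-corrected H, chi-square p with k−1 df); because the cohorts of
interest are small, `kruskal_wallis()` adds an exact permutation p that
enumerates every distinct assignment of observations to groups of the
observed sizes (automatic up to total n = 10, where the largest
enumeration is 4200 assignments). The significance level 0.05 is reported,
never enforced.

## Numerical choices and degenerate inputs

* Ct values must lie in [0, 45] (instrument range); anything else is a
  parse error, and the tokens `Undetermined`/`NA`/empty map to
  undetermined. Unicode minus signs are folded to ASCII hyphens in both
  assay IDs and numbers, since typeset tables use them.
* Global-mean normalization requires at least 2 detected assays; the
  degenerate all-identical Kruskal–Wallis input returns H = 0, p = 1.
* Comparison tables are written sorted by descending fold regulation with
  ties broken by assay ID, at 2 decimals; write-then-read is the identity
  at printed precision.
* `FR(ddCt = 0)` is +1 by convention; antisymmetry `FR(A vs B) = −FR(B vs A)`
  holds except at `FC = 1`, where both directions report +1.

## Problem sizes

The test suite and the reproduction script run the full 372-assay,
3×10-sample cohort for recovery checks (the size of the design being
emulated), 20 planted effects with |log2 effect| in [1, 7], and exact
Kruskal–Wallis enumeration up to n = 12; the complete suite runs in a few
seconds on one CPU.

## Known limitations

* The packaged 372-target panel pads the published mature IDs with
  synthetic placeholders; it is a stand-in for an unpublished commercial
  assay list and is labelled as such.
* Pooled designs have no within-group replication: fold-regulation
  thresholds are effect-size heuristics, and no p-values are attached to
  miRNA calls. This mirrors the emulated workflow; it is not a statistical
  endorsement of it.
* Printed-table reproduction is limited to 2-decimal precision, and two
  published summary counts that conflict with their own table's row counts
  are not reproduced (the table is taken as authoritative).
* Mean-centric normalization biases fold regulations when the true
  signature is strongly asymmetric (see the generator section); the
  package exposes reference-gene and spike-in alternatives and a
  concordance report to quantify the disagreement.
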