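---
title: "Grading soil fertility with attribute recognition and entropy weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading soil fertility with attribute recognition and entropy weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilgrade)
```

## The problem

Soil fertility is a multi-indicator property: organic matter (SOM, %),
total and hydrolysable nitrogen (N_total %, N_hydro mg/kg), total and
available phosphorus (P_total %, P_avail mg/kg) and available potassium
(K_avail mg/kg) each tell part of the story, and no single index ranks
sites on its own. In land-use comparisons and restoration
chronosequences (sites abandoned for 0, 5, 10, 15, 20, 25 years,
sampled with five replicates per group) one wants a per-sample fertility
grade and score that aggregates all six indexes against an agronomic
grade standard, plus the usual group statistics. `soilgrade` implements
that pipeline: attribute measures against a grade standard matrix,
entropy weighting of the indexes within each group, confidence-criterion
grade classification, score ranking, and group summaries with one-way
ANOVA and compact letter displays.

## The model

### Grade standard matrix

A standard matrix fixes, per index $j$, the $K-1$ boundary values
$a_{j1} > a_{j2} > \dots > a_{j,K-1}$ separating $K$ ordered fertility
grades (grade 1 best, grade $K$ worst; reversed boundary order for
`lower_is_better` indexes). The shipped default
(`inst/extdata/grade_standard_6.csv`, loaded by `default_standard()`)
has $K = 6$ grades for the six indexes, following commonly tabulated
national soil-nutrient survey levels. It is deliberately a plain,
editable fixture: the thresholds are configuration, not code, and $K$
is data-driven everywhere — a 2-grade or 8-grade standard works
unchanged.

### Single-index attribute measures

The attribute measure $\mu_{ijk} \in [0,1]$ is the degree to which
sample $i$'s value of index $j$ belongs to grade $k$, with
$\sum_k \mu_{ijk} = 1$. We use the canonical piecewise-linear
construction: each grade has an anchor point where its membership is
exactly 1 (the midpoint of its boundary interval for interior grades;
edge anchors extend half an adjacent interval width beyond the outermost
boundaries), membership is exactly 0.5/0.5 at every shared grade
boundary, values beyond the edge anchors belong fully to the edge grade,
and membership is linear between these knots. This form keeps the
boundary tie-rule closed (0.5/0.5, no epsilon), makes the measure vector
a distribution supported on at most two adjacent grades, and makes the
cumulative measure monotone in the nutrient value. A second mode,
`anchor = "boundary"`, places the anchors on the boundaries themselves
and ramps between consecutive boundaries; which anchoring an assessment
uses is an explicit, logged choice (`midpoint` is the default), since
field practice varies and the two coincide only for equal-width grades.
A `lower_is_better` index is handled as the exact mirror image: same
construction on the reversed boundary vector with the grade order
reversed.

Missing index values are a hard error by default (`na_action =
"error"`); silent imputation would distort the entropy weights computed
from the same columns. `na_action = "drop"` discards affected samples
explicitly.

### Entropy weights

Within each group (a land use, or one restoration age) with $n$
replicates, index weights come from Shannon entropy of the normalized
column shares $p_{ij}$:

$$H_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}, \qquad
  d_j = 1 - H_j, \qquad w_j = d_j \Big/ \sum_j d_j,$$

with $0\ln 0 \equiv 0$. An index whose replicates are nearly identical
carries no discriminating information ($H_j \to 1$, $w_j \to 0$); a
dispersed index gets more weight. Two normalizations are exposed:
`proportional` ($p_{ij} = x_{ij}/\sum_i x_{ij}$, the default — weights
are then invariant to rescaling an index's units) and `minmax`
(min–max rescale, then shares). Degenerate cases follow continuity
limits: a constant column gets weight 0; if every column is constant the
equal-weight fallback $1/m$ is returned with a warning. Because the
literature rarely states which variant of the entropy-weight
construction was used, both the share normalization and whether entropy
is taken over raw values (`mode = "raw"`, default) or over per-sample
grade scores of the attribute measures (`mode = "measure"`) are explicit
configuration, echoed into every output file.

### Synthesis, classification, scoring

The comprehensive measure is the weighted mixture
$\mu_{ik} = \sum_j w_j\,\mu_{ijk}$ — a convex combination of
distributions, hence itself a distribution over grades. The grade is
assigned by the confidence criterion

$$k^\ast = \min\Big\{k : \sum_{l \le k} \mu_{il} \ge \lambda\Big\},$$

with $\lambda \in (0.5, 1]$ (the criterion is ill-posed at or below
0.5). The default $\lambda = 0.7$ is the conservative end of the
conventional 0.6–0.7 range; it is a required, logged parameter, and
raising it can only move a sample towards worse grades. Ties (cumulative
measure exactly $\lambda$) assign that grade — a closed deterministic
rule. The score $q_i = \sum_k c_k \mu_{ik}$ with default grade values
$c_k = K + 1 - k$ ranks samples continuously (grade-1 certainty scores
$K$); it is strictly monotone under first-order stochastic dominance of
the grade distribution.

### Group statistics

`summarize_groups()` reports the sample mean, SD (with the $n-1$
denominator, so CV comparisons across groups are well defined) and CV
per group and index. `oneway_anova()` is the classical fixed-effects F
test (via `stats::lm`); when every group has zero within-group variance
the F statistic is undefined and the documented degenerate rule applies
(p = 0 if any means differ, else 1, with a message). Multiple-comparison
letters use pairwise least-significant-difference t tests on the pooled
ANOVA mean square with greedy compact-letter assignment in
descending-mean order — a deliberate, documented replacement for
SPSS-style Duncan grouping, whose exact replication is out of scope.
`weight_spread()` quantifies how unequal a group's index weights are,
as a relative range in percent; both candidate formulas are implemented
— `range_over_min` ($(\max_j w_j - \min_j w_j)/\min_j w_j \times 100$,
default) and `range_over_mean` — and the method used is recorded in the
output, since the published "largest difference between weights"
statistic is not accompanied by a formula. The spread is 0 exactly when
all weights are equal. With only 5 replicates per group the minimum
weight can be very close to zero, making `range_over_min` extremely
volatile; `range_over_mean` is the steadier choice at the study's
replicate counts.

## The synthetic-data generator

The study's raw 52-sample matrix was never published, so the generator
is a first-class module that emulates the design from the published
group summaries:

* **Land uses** — farmland, artificial grassland, natural grassland,
  woodland, shrubland; per-index means and CVs as published
  (`landuse_params()`), 5 replicates each.
* **Chronosequence** — ages 5–25 years with published means and SDs
  (`restoration_params()`); the published dispersions for the 0-year row
  are inconsistent between the two source tables (the same numbers
  appear once captioned as CVs and once as SDs), so the 0-year control
  reuses the farmland mean/CV parameters and the parenthetical values
  for ages 5–25 are taken as SDs (their magnitudes only make sense that
  way).
* **Composition** — `study_fixture()` emits 5 land uses × 5 + ages 5–25
  × 5 + 2 extra farmland replicates, with farmland doubling as the
  0-year control (n = 7), totalling exactly 52. The published sample
  count is not decomposable from the printed information; this
  composition is the package's own documented choice, flagged rather
  than silently resolved.

Draws are lognormal by default (nutrient concentrations are positive and
right-skewed), with the parameters moment-matched so the distribution's
true mean and CV equal the specification exactly
($\sigma^2 = \ln(1+\mathrm{CV}^2)$,
$\mu = \ln(\text{mean}) - \sigma^2/2$); a zero-truncated normal is
offered for sensitivity analysis, with the caveat that truncation shifts
the realized mean upward at large CV. Indexes are drawn independently
within a sample (within-group covariance is unreported); an
equicorrelation knob `rho` exists but defaults to 0. Seeds are mandatory
arguments, and each group label gets its own deterministic substream, so
adding or reordering groups never perturbs the others' draws.

What the generator does *not* emulate: spatial correlation among plots,
soil-depth structure, measurement error, or any real covariance between
indexes. Tests passing on synthetic tables therefore validate the
*method's* invariants and statistical behaviour, not claims about any
particular real landscape.

## Numerical choices

* Measure normalization is exact by construction; tests enforce
  $\sum_k \mu_{ijk} = 1$ to $10^{-9}$ across $10^4$ random cases.
* Entropy: divergences are clamped at 0 against floating-point
  round-off; the all-uniform fallback triggers when
  $\sum_j d_j < 10^{-12}$.
* Classification uses the exact $\ge \lambda$ comparison (matching the
  linear-scan definition); if rounding leaves the final cumulative sum
  marginally below $\lambda = 1$, the worst grade is returned.
* Weights are reported to 2 decimals as percents in tabular output;
  internal precision is full.

## Workflow and problem sizes

The `analysis/` scripts run the three pipeline stages
(`01_simulate.R` → `02_assess.R` → `03_summarize.R`) on the 52-sample
synthetic table and write their tables under `results/`, each with a
provenance header carrying the full configuration. The same computations
are available programmatically via `run_simulate()`, `run_assess()` and
`run_summarize()`, and `scripts/acceptance.R` recomputes the headline
quantities from scratch for a given seed. Test problem sizes were chosen
to make the statistical checks sharp yet quick: moment-recovery and
trajectory-ordering checks use $n = 10^4$ draws per group (mean within
2%, CV within 5%), oracle comparisons use 500–1000 random datasets, the
dispersion-discrimination check uses 200 replicates of $n = 50$ groups,
and the weight-convergence simulation uses a 6-age chronosequence with
$n = 500$ per age whose per-index CVs converge linearly to a common
value — large enough that entropy-weight noise cannot mask the
convergence signal.

```{r example}
st <- study_fixture(seed = 1)
out <- assess(st, default_standard(), lambda = 0.7)
weights_table(out$weights)[1:3, ]
table(out$results$grade)
```

## Known limitations

* The published per-group weight tables cannot be recomputed without the
  original raw sample matrix, and the exact entropy-weight variant used
  there is unstated; this package fixes and documents its own defaults
  instead of attempting a numerical match.
* Compact letters use pairwise LSD, not Duncan's multiple range test;
  letterings can differ from SPSS output for borderline pairs.
* At $n = 5$ replicates entropy weights are noisy; group weights and
  spreads from such small groups should be read as descriptive, not
  inferential.
* Grade assignment is per sample; group-level recognition (classifying
  a group's mean measure) is intentionally out of scope.
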