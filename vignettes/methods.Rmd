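---
title: "Appraising approval dossiers: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising approval dossiers: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eparmeta)
```

## The problem

A marketing-authorisation dossier (an EPAR, in the European system) lists
the randomised trials behind an approval, but the results are reported at
four levels of completeness: full per-arm statistics; only the contrast
between arms with its standard error; only a p-value with group sizes; or
nothing usable. `eparmeta` standardizes whatever is reported into Cohen's
*d*, pools per drug and daily dose with a random-effects model, and grades
each approval's evidence against an explicit rubric. This vignette is the
package's account of the underlying models, the choices that were genuinely
open, and what the test battery does and does not establish.

## The effect-size cascade

Every investigational-vs-comparator contrast is dispatched to the richest
tier its reporting supports (`arm_stats > contrast_only > p_and_n_only`),
and the result always carries the tier that produced it.

**Sign convention.** Negative *d* favours the investigational drug,
regardless of whether the outcome scale improves downwards
(`better_is = "lower"`, symptom scales) or upwards (`"higher"`, response
rates), and regardless of whether a binary event is desirable. All
orientation handling happens inside the cascade; downstream code never
re-signs.

**Continuous arms.** `d = (m_inv − m_comp)/s_pooled` with the bias-free
pooled SD, `var(d) = (n1+n2)/(n1 n2) + d²/(2(n1+n2))`. The small-sample
(Hedges) correction is available (`hedges = TRUE`) but off by default:
dossier appraisal conventions report plain Cohen's *d*, and pivotal trials
are large enough (hundreds per arm) for the correction factor to be
negligible.

**Binary arms.** The log odds ratio is mapped to *d* by the logistic-scale
conversion `d = ln(OR)·√3/π` with `var(d) = (3/π²)·Σ 1/cell`. A 0.5
continuity correction is added to all four cells exactly when some cell is
zero. When both arms have no events (or both all events) the table carries
no comparative information: the estimate is flagged `degenerate`, excluded
from pooling, and never silently imputed.

**Contrasts.** `t = contrast/se`, `d = t·√(1/n1 + 1/n2)`. For equal arm
sizes and a Welch-type SE this is algebraically identical to the
`arm_stats` result, which the test suite exploits as a cross-path oracle.

**p-and-n imputation.** `|t|` is the upper `p/2` quantile of the central
*t* with `df = n1 + n2 − 2` (computed on the upper tail so very small
p-values keep full precision), scaled by `√(1/n1 + 1/n2)` and signed by the
reported direction. A p-value reported *without* a direction cannot be
signed; guessing a sign would manufacture evidence, so such comparisons are
counted with the insufficient tier.

**Which p-value?** A design fork with no universally right answer: the
meta-analytic convention refers `d/se(d)` (whose variance includes a `d²`
term) to a reference distribution, while the trial itself reported the
two-sample *t* statistic `t = d/√(1/n1+1/n2)`. The package uses the latter
for continuous outcomes, for two reasons: it is the p-value the dossier
actually printed, and it makes derivation and imputation exact inverses of
one another — the imputation tier recovers *d* to numerical precision
(tested at 1e−6). Binary outcomes refer the log-OR ratio `d/se(d)` to the
same *t* reference, the natural test on that scale. Significance is always
two-sided at α = 0.05.

## Random-effects pooling

Pooling keys are (approval, drug, daily dose, design phase, comparator
class): initiation and continuation designs never share a key, nor do
active and placebo comparators, and each dose arm of a multi-arm trial
contributes its own comparison to its own key, without a shared-control
correlation correction — comparisons are treated as independent records, as
dossier appraisal treats them. A switch (`by_indication = FALSE`) pools
across indications within drug/dose for sensitivity analyses.

The estimator is the classic DerSimonian–Laird moment estimator with τ²
truncated at zero and a Wald normal CI. REML, Paule–Mandel and
Hartung–Knapp are deliberately out of scope: the package's claims are tied
to the field's long-standing default, and the test suite pins the
implementation to an independent brute-force evaluation of the defining
formulas (1,000 random meta-analyses at 1e−10) and to `metafor`'s
`method = "DL"` (1e−8).

**Dose filter.** Effect sizes and meta-analyses cover approved dosages
only: a comparison whose investigational arm dose lies outside
`[approved_dose_min, approved_dose_max]` is excluded before triage and
pooling (the benchmark corpus contains one entirely dose-excluded study).
Arms without a recorded dose are retained; an approval with dose-bearing
arms but no recorded bounds triggers a warning and retains its arms —
silently discarding evidence would be worse than a loud assumption.

## The grading rubric

Per trial and comparator class: **positive** if the primary comparison is
statistically significant in the drug's favour; **negative** if a
comparison was reported but was not significant or favoured the comparator;
**uncompared** if a comparator arm was randomised but never compared with
the drug (the "internal positive control for assay sensitivity" pattern).
Non-inferiority trials use the dossier's reported verdict; when none was
recorded but an outcome-scale contrast CI and a non-inferiority boundary
are available, the trial is positive when the CI bound on the unfavourable
side stays within the boundary. Pooled non-inferiority analyses are
represented as analysis-level trial records flagged `pooled_analysis` and
counted per analysis — that is how assessors counted them.

Per approval and rubric column: `robust` (≥ 2 positive), `single` (exactly
one positive, negatives allowed), `none` (only negative, uncompared, or no
study), `not_required` (the dossier waived the comparison class). The
grouped active/placebo columns take the *stronger* of the initiation and
continuation categories rather than summing positives: one positive
initiation and one positive continuation trial are each single-study
evidence for their design, not jointly robust evidence for either.

Grading uses the evidence as presented (no dose filter): a dossier's
evidentiary claims are judged on what it contains, while quantitative
pooling is restricted to approved doses.

**Percentages.** Integer percentages are rounded half away from zero, with
the raw fraction always emitted alongside — integer rounding of these
denominators is lossy (21/26 is 80.77%), and downstream consumers should
not have to re-derive the fraction. Denominators exclude `not_required`
approvals; an empty denominator yields an explicit `NA`, never a zero.

## The synthetic generator

`generate_corpus()` simulates the statistical structure the pipeline
assumes. Per trial, a true standardized effect
`δᵢ ~ Normal(true_effect, τ²)` for its comparator class; continuous
outcomes have unit true SD with the drug arm shifted by δᵢ (lower better),
and sampling noise enters through the simulated per-arm summary statistics;
binary outcomes fix the comparator event rate (default 0.4) and set the
drug rate so the log-OR conversion equals δᵢ exactly. Reporting is then
censored per comparison into one of the four tiers; the `contrast_only`
tier keeps the observed difference and SE, `p_and_n_only` keeps the
realised p, group sizes and direction, `insufficient` blanks everything. A
binary result drawn into the `contrast_only` tier reports full arm
statistics instead, because a proportion difference is not an outcome-scale
contrast. One root seed with per-approval substreams makes corpora
reproducible and extensible: adding approvals never perturbs earlier ones.

Defaults encode the study conditions the package's checks are run at: five
trials per approval, 100 subjects per arm, a modest true placebo benefit
(d = −0.3) with heterogeneity τ² = 0.05, no true difference against active
comparators, 80% continuous outcomes, and a tier mix (0.60 / 0.10 / 0.05 /
0.25) matching the observed completeness of real dossier corpora.

What the generator does **not** emulate: dropout and missing-data
mechanisms, flexible-dose titration (doses are fixed labels), cross-over
and cluster designs, survival outcomes, correlated multi-arm sampling
error, selective reporting correlated with effect size, and any text-level
features of dossiers. Passing tests therefore show that the pipeline is
internally consistent and recovers known truth under clean conditions — not
that real extractions are free of those complications.

## The benchmark corpus

`benchmark_corpus()` builds a deterministic, schematic 27-approval corpus
(137 trials, 267 comparisons) whose *marginal* tallies — rubric categories
per column, the four-tier reporting split 158/29/12/67 over 266
dose-eligible comparisons in 136 studies, route and flag margins — are
meaningful, while individual approvals beyond a few named exemplars
(olanzapine, varenicline, duloxetine, paliperidone, agomelatine, nalmefene)
are arbitrary constructions at n = 100 per arm and unit SD. It ships both
as code and as a CSV bundle under `inst/extdata/benchmark_corpus`, and a
test pins the two representations together, so acceptance checks are
independent of generator drift. Flag assignments beyond the documented
margins are arbitrary and should not be interpreted.

## Numerical choices

- τ² truncation at zero (the moment estimator can be negative); with τ² = 0
  the pool reduces exactly to inverse-variance fixed effects (tested).
- `qt(p/2, df, lower.tail = FALSE)` rather than `qt(1 − p/2, df)`: the
  latter saturates for p below machine epsilon.
- k = 1 pools return the study unchanged with τ² = 0 by definition.
- Equal-proportion binary tables give d = 0 exactly; degenerate tables give
  `NA` plus a flag rather than a continuity-corrected pseudo-estimate.
- Record ordering in written corpora is sorted by id, and field order
  follows the schema, so serialisation is byte-stable (tested); missing
  values are empty cells/JSON nulls, never sentinel zeros.
- Stratum medians use the sample median (mean of middle two for even
  counts); an empty stratum reports `n_keys = 0` with `NA` statistics.

## Problem sizes and known limitations

The stochastic checks run at: 500 simulated corpora (k = 5 trials, 100 per
arm, d = −0.3, τ² = 0.05) for parameter recovery and CI coverage; 500
null-hypothesis trials for the false-positive rate; 300 + 300 corpora for
the censoring-robustness comparison. At these conditions mean recovery is
well within ±0.02 of truth, the null rejection rate is nominal, and tier
censoring shifts the pooled mean by under 0.03 — but the DerSimonian–Laird
Wald interval covers the true effect in only ~89% of replicates, the
well-documented undercoverage of that interval with few, heterogeneous
studies. The package reports it as measured rather than substituting a
different estimator, and the acceptance battery records the coverage check
against a 0.90 floor as failing for exactly this reason. Users pooling
k ≤ 10 studies should read the Wald CI as approximate.

Other limits: no effect sizes for cross-over, cluster-randomised or
time-to-event designs; no multiplicity adjustment of trial p-values; no
publication-bias diagnostics; comparisons from the same multi-arm trial are
pooled as independent.
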