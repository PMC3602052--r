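---
title: "Benchmarking health systems with stage-specific relative survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking health systems with stage-specific relative survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survbench)
```

## The problem

Cancer registries publish, per region and period, the distribution of new
cases over disease stages together with stage-specific and overall
*relative survival* — observed patient survival divided by the expected
survival of a demographically matched background population. Relative
survival absorbs background mortality, so no cause-of-death coding or
competing-risk modelling is needed, and every patient contributes.

`survbench` turns such summary tables into a comparison of health-care
"objects" (countries, states, districts, registries) against a fixed
*reference object*, the designated best performer. Every index is an
observed-over-expected ratio

$$\mathrm{index} = O / E^{*},$$

where \(E^{*}\) is the reference's value of the same quantity. In a
*cross-sectional* run all benchmark objects come from the reference's
period; in a *longitudinal* run the reference stays fixed in time while
benchmark objects span periods, tracing trajectories.

## The indices

Let object \(X\) have \(N\) cases, \(N_i\) of them at stage \(i\) (ordinal
codes; by default clinical stages 0–4 plus an "unknown" stage coded 5),
with stage-specific relative survival \(\mathrm{RSR}_i\) and overall
relative survival \(\mathrm{RSR}\).

**eSSI (extended standardized screening index).** The stage-weighted mean
\(\sum_i (N_i/N)\,w_i\) with weights \(w_i = i\) by default, taken as a
ratio of benchmark over reference. Values below one mean case mass sits at
earlier stages than in the reference — the footprint of effective
screening. The stage-number weights are admittedly arbitrary (they give
stage 0 no weight and the unknown stage the most), so `essi()` accepts any
non-negative weight map, including one that drops the unknown stage
(`default_stage_weights(include_unknown = FALSE)`); the default keeps all
stage rows of the conventional table layout.

**SCI (standardized case-mix index).** The survival-weighted case mix
\(\sum_i N_i\,\mathrm{RSR}_i / N\), again as a benchmark/reference ratio.
It summarises how favourable the stage mix is and serves as the risk
adjuster inside STI.

**SWI (standardized work-up index).**
\(\bigl(\sum_{i\in S} \mathrm{RSR}_i^{O}/\mathrm{RSR}_i^{E^*}\bigr)/|S|\):
the mean over shared stages of the stage-wise survival ratios. The divisor
is the *number of represented stages*: the set \(S\) contains the stages
where both objects report a rate, the reference rate is positive, and (by
default, switchable via `require_cases = FALSE`) both objects actually
have cases at the stage. Only shared stages yield defined ratios; the
alternative reading of the divisor as a case count is dimensionally
inconsistent and is not implemented.

**STI (standardized treatment index).**
\((\mathrm{RSR}^{O}/\mathrm{RSR}^{E^*}) / \mathrm{SCI}\): the overall
survival ratio, case-mix adjusted. It probes treatment effectiveness net
of the stage distribution.

**Composites.** \(\mathrm{OPE} = \mathrm{SCI}\times\mathrm{SWI}\times
\mathrm{STI}\) and \(\mathrm{ROPI} = (1/\mathrm{eSSI})\times\mathrm{SWI}
\times\mathrm{STI}\). The screening index enters ROPI as a reciprocal so
that larger is uniformly better; ROPI also avoids OPE's partial
self-cancellation (SCI appears in STI's denominator). Both factorizations
are maintained to 1e-12 by construction, and `index_panel()` refuses to
return non-positive or non-finite values — degenerate references (zero
weighted mean, zero survival) are loud errors, never `NaN`s.

Reading the numbers: an index of exactly one is the reference itself
benchmarked against itself — the anchor row every run reproduces. Above
or below one flags an advance or a gap; `interpret_panel()` renders the
sign conventions in words, with a configurable neutrality band (default
±0.005, i.e. indistinguishable at the three printed decimals; no
established clinical threshold exists, so the band is presentational, not
inferential — the package deliberately computes no p-values).

## Data model and validation

Input is a long-format CSV, one row per (object, period, stage), with a
designated *total* row (default stage code 6) carrying `n_total` and the
overall rate, and a designated *unknown* stage (default 5); codes and
column names are remappable via `long_table_schema()` for other diseases
or staging nomenclatures. `read_long_table()` enforces:

* stage counts sum *exactly* to the total (mismatch is an error, never
  auto-corrected — benchmarking demands accurate, complete data);
* unique stage codes per object, positive totals, rates within
  \([0, 120]\) percent (relative survival may legitimately exceed 100%);
* one survival scale per object. Rates all at or below 1.2 are read as
  fractions and normalised to percent; any rate above 1.2 marks a percent
  object, and a mixture is a validation error. The 1.2 threshold
  separates the scales unambiguously for real survival data. Because
  normalisation happens at construction and every index is a ratio, the
  percent/fraction choice cannot change any result.

Violations are *reported* (`validate_objects()` returns a tibble naming
object, period, rule) rather than thrown, so a 17-registry run does not
die on one bad registry: the engine drops offenders with a warning, or
aborts when `strict = TRUE`.

The reference object is selected by (`reference_id`, `reference_period`)
at run time; reference and benchmark objects share one schema rather than
prefixed duplicate columns, which keeps a single parser and lets any
object serve as reference.

## The synthetic generator

`generate_objects()` emulates the qualitative structure of registry
summary tables so everything is testable without any registry extract:
multinomial stage counts around baseline probabilities
`c(0.02, 0.40, 0.35, 0.10, 0.05, 0.08)` (a mammography-era breast-cancer
mix: mass in stages 1–2, little in-situ and metastatic disease, a modest
unknown share), an exponential `skew` tilt that moves mass toward earlier
(positive) or later (negative) stages, survival baselines
`c(98, 97, 85, 60, 24, 75)` percent — monotone declining over clinical
stages with the unknown stage in between — under multiplicative
log-normal noise (sd 0.03 stage-wise, 0.01 overall, clipped to
(0, 120]), and totals drawn from 5,000–50,000, a plausible span from
district registries to small national ones. The overall rate is the
case-weighted mean of the stage rates times the noise factor, so
generated objects are internally coherent and always pass validation.

Generation is a pure function of (config, seed): the seed is mandatory,
and the caller's RNG stream is left untouched. `shift_stage_mass()`
provides controlled stage migration for monotonicity checks.

What the generator does *not* emulate: stage-migration artefacts
(Will-Rogers reclassification), lead-time bias, correlated noise across
periods, or any real registry's actual values. Passing tests therefore
demonstrate the algebra, invariances and plumbing of the method — not
that any particular health system comparison is clinically meaningful.

## Numerical and design choices

* No rounding inside computations; three decimals only at presentation
  (the text report), full `%.17g` precision in the results CSV so written
  tables round-trip bit-exactly.
* Cross-sectional tables sort by ROPI descending by default (the
  composite the method prefers); configurable via `sort_key`.
* Period labels are opaque strings ordered by first appearance or an
  explicit `period_order` — never parsed as dates, since registry periods
  are intervals like "1999-2003". Each label is one ordinal tick in
  longitudinal plots.
* Trend plots draw one line per group with a dashed anchor line at 1.0
  always inside the y-range, linear axis; styling is fixed and
  deterministic.
* Problem sizes in the shipped tests are desk-scale by design: identity
  and oracle checks on printed or tiny tables, randomized property suites
  of 200 cases, and an end-to-end run of 2 groups × 7 periods — ample to
  pin down ratio arithmetic whose cost is trivial at any scale.

## Scope and limitations

The package consumes precomputed relative survival rates; estimating them
(Ederer II, period or cohort life tables) is out of scope, as are
significance tests for index differences (no distribution theory exists
yet for these ratios) and peer-group clustering of benchmark objects.
Comparisons are only as fair as the inputs: identical staging
nomenclature, comparable life tables and complete case ascertainment
across objects are the user's responsibility.

## A worked run

```{r example}
cfg <- synthetic_config(n_objects = 2, periods = paste0("P", 1:7),
                        skew = 0.2, seed = 400)
objs <- generate_objects(cfg)
run <- run_config("longitudinal", reference_id = "obj01",
                  reference_period = "P7")
tb <- longitudinal(objs, run)
tb
interpret_panel(tb[1, ])
```

```{r plot, fig.width = 7, fig.height = 4.5}
plot_index_trend(tb, index = "ropi")
```
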