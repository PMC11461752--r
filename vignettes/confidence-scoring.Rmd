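---
title: "Scoring confidence in citizen-science observations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring confidence in citizen-science observations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsconf)
```

## The problem and the model

Unverified citizen-science records carry uncertainty from three sources:
the species being identified, the media documenting it, and the
georeference locating it. `obsconf` scores each source separately and sums
the step scores into a single ordinal confidence level, so that a
researcher can triage thousands of records consistently and justify which
ones enter an analysis.

The rubric is deliberately not probabilistic. Each step is a small lookup
table over human-assessable categories, and the only arithmetic is a sum
and a binning. This keeps the procedure fast to apply, auditable, and free
of the assessor-to-assessor drift that unstructured expert review suffers
from. The cost is granularity: the output is one of three bands (plus
"unscorable"), not a calibrated probability of correctness.

### Steps, stop points, precedence

* **Species step.** Input is a per-species trait registry: diagnostic
  visibility (`easy_to_see`, `visible_with_difficulty`,
  `requires_dissection_or_molecular`) crossed with whether a very similar
  species occurs in the region. Default points 7 / 5 / 3 / 1. The
  `requires_dissection_or_molecular` level is a stop: no field photograph
  can settle the identification.
* **Media step.** Clarity (`clear`, `moderate`, `poor`, `unusable`)
  crossed with diagnostic features shown (`all`, `most`, `some`, `none`).
  `unusable` clarity and `none` shown are stops. The media assessment is a
  human (or upstream-tool) annotation supplied with the record, not
  computed from pixels — scoring judgement calls from images would make
  the tool non-deterministic and untestable.
* **Georeference step.** Positional accuracy radius binned at 1 km and
  10 km (half-open, lower-inclusive: a radius of exactly 1000 m falls in
  the middle bin, because "less than 1 km" is a strict inequality).
  Missing coordinates are a stop.

When several steps stop at once, the reported reason is the first in step
order (species, media, georeference), matching the order in which the
protocol is applied.

The species and media tables span 1–7 while georeference spans 2–4: more
factors bear on the first two sources of uncertainty, and the
configuration validator enforces that asymmetry (`validate_rubric_config`
rejects tables whose georeference range is as wide as either of the other
two, or whose attainable totals leave the band range).

### Banding

Totals span exactly 4–18 and are banded low = 4–8, medium = 9–13,
high = 14–18. Band edges are inclusive integers; totals are integer sums,
so no rounding is involved. `enumerate_rubric()` crosses every non-stop
level and is used by the tests to verify that the attainable totals cover
the range and that every total lands in exactly one band.

### Degraded inputs

A record with coordinates but no stated accuracy radius is common in
platform exports. By default it receives the *lowest* georeference points
with a warning — absence of a radius degrades confidence but does not void
the record, since the stop is defined for missing coordinates only.
`strict_geo = TRUE` switches to treating it as a georeference stop, for
users who consider an unstated radius equivalent to no georeference.

## Validation statistics

Confidence is validated against expert accuracy labels (`incorrect` <
`uncertain` < `correct`) and against the platform quality grade (`casual`
< `needs_id` < `research_grade`) with Kendall's rank correlation in its
tie-corrected (tau-b) form. With a handful of ordinal levels over hundreds
of records, ties dominate: the uncorrected variant is structurally unable
to approach ±1, so tau-b is the only defensible choice. The
implementation counts concordant and discordant pairs from the
contingency table of level combinations and exposes C, D and the tie
terms n₁, n₂ alongside tau; tests check it against a brute-force
enumeration of all pairs and against `stats::cor(method = "kendall")`.

Two-sided p-values use the normal approximation
z = 3(C − D) / √(n(n−1)(2n+5)/2), which is accurate at the sample sizes
this package targets (hundreds to thousands). Sequences with zero variance
raise an error rather than returning NaN. Strength is interpreted on the
conventional bands — below 0.10 negligible, then weak, moderate at 0.40,
strong at 0.70, very strong at 0.90 — lower-bound inclusive.

### Unscorable records in correlations

Whether unscorable observations belong in a confidence–accuracy
correlation is a genuine design fork. The default here includes them as
the lowest confidence rank: they are a real output of the protocol, they
appear in the case study's own breakdowns, and dropping a third of the
data changes what the correlation describes. `include_unscorable = FALSE`
is available to drop them pairwise (the dropped count is reported).

The choice matters quantitatively. With unscorable ranked lowest, the
case-study marginals (358 of 957 unscorable, 333 uncertain) cap the
attainable tau-b well below 1 even for the maximally concordant joint
fill — the packaged fixture realises exactly that ceiling, and
`scripts/acceptance.R` prints it (`fixture_confidence_accuracy_tau`).
Published correlations on comparable data that exceed this ceiling must
therefore have excluded unscorable records or coded them differently;
users comparing against external analyses should check that choice first.

### Rounding

Report percentages are rounded half-up to one decimal (`round_half_up`),
not with banker's rounding, and only at formatting time; unrounded values
travel alongside (`raw_pct`, `retained_fraction_raw`). Note that half-up
rounding of a correct count ratio can differ by 0.1 from a percentage
printed in a source that rounded differently; this package always reports
the value computed from the counts.

## The synthetic generator

`generate_dataset()` exists so every stage — parsing, scoring,
correlation — is testable against known ground truth without downloading
anything. One latent record-quality value u ~ U(0,1) drives everything:

* species level by quartile of u (points 1/3/5/7),
* media level by quartile (points 1/3/5/7),
* accuracy radius by third (20 km / 5 km / 100 m).

Under the default tables the rubric total is then a monotone step function
of u whose band transitions fall exactly at u = 1/3 and u = 2/3. The true
accuracy label is, with probability |association|, the matching thirds map
of u (and `uncertain` for records driven into a stop, mirroring expert
practice of labelling unverifiable records uncertain); otherwise it is
uniform over the three classes. This mixture makes the two extremes exact:
`association = 1` with `stop_rate = 0` yields tau-b = 1 through the whole
pipeline, and `association = 0` yields independence — both are asserted in
the tests, along with monotone recovery of intermediate values.

Stops are injected independently at `stop_rate`, rotating through the
three stop kinds. Quality grade follows accuracy (correct →
research grade, otherwise needs ID) with probability 1 − `grade_noise`,
otherwise it is drawn from a fixed background mix (57% research grade,
42% needs ID, 1% casual) — the platform's grade reflects community
engagement and metadata completeness at least as much as correctness, so
its default coupling to accuracy is weak.

Defaults (`n = 957`, `association = 0.8`, `stop_rate = 0.37`,
`grade_noise = 0.9`) emulate the structure of the marine alien-species
case study this package ships as a fixture: roughly a thousand records, a
strong confidence–accuracy relationship, about 37% unscorable, and a
quality grade that is only weakly informative about accuracy. What the
generator does **not** emulate: real spatial and temporal clustering of
observers, per-taxon observation-volume imbalance, correlated media and
georeference quality within an observer, and label error in the expert
verification itself. Passing tests on synthetic data therefore demonstrate
that the machinery recovers the associations it was built to measure, not
that any particular field dataset will show them.

### The case-study fixture

`case_study_fixture()` rebuilds a 957-record scored set whose
confidence-band, accuracy and quality-grade *marginals* equal the case
study's printed counts exactly. Joint cells are a deterministic fill —
records laid out in descending band order with accuracy and grade labels
dealt best-to-worst — which maximises rank concordance subject to the
marginals; no claim is made about the study's joint distribution. The
unscorable block is split 197 records stopping at the species step
(molecular-only taxa, 20.6% of the total) and 161 at the media step.
Rubric inputs are chosen per band so that the bands in the fixture come
from actually running `score_set()`, not from assignment. The registry
shipped in `inst/extdata/` carries the case study's 36 species; its
molecular/dissection flags follow the published species list, while the
remaining trait levels are illustrative assignments (marked as such in the
`notes` column) chosen to cover the rubric's levels.

## Problem sizes and numerical choices

Property-style tests run the tau implementation against the all-pairs
oracle on hundreds of random tied instances of n ≤ 30, and pipeline
recovery uses n = 2000 records over five seeds per association level —
large enough that sampling noise in tau (≈0.015 at n = 2000) is an order
of magnitude below the effects being checked, small enough to keep the
whole suite under a minute of compute. The acceptance script uses the same
sizes. All generator randomness flows from a single integer seed, and the
generator restores the caller's RNG state.

## Known limitations

* The rubric presumes the assessor knows the listed species' diagnostic
  features; the registry encodes that knowledge but cannot replace it.
* Media assessment is an input, so two assessors can still disagree
  upstream of the deterministic scoring.
* The land/sea plausibility test ships only as a toy rectangular mask;
  production use should supply a predicate backed by a real coastline
  dataset.
* Confidence bands are ordinal, not calibrated probabilities; comparing
  absolute band shares across taxa with different registry difficulty
  profiles conflates species mix with record quality.
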