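---
title: "Methods: resampling analysis of agonistic encounter data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling analysis of agonistic encounter data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agonistics)
```

## The problem and the data model

Territorial reef fishes settle most contests over food without
fighting: an intruder is recognized as a competitor, and the encounter
ends passively, with a ritualized visual signal, or with an escalated
chase. How well this competitor-recognition process works should differ
between conspecifics (familiar signals, shared fighting ability) and
heterospecifics, and it can be perturbed when a resource crash
reshuffles which species actually compete. The package analyses
focal-individual encounter records collected around such a crash.

An encounter record holds: region, reef, period (`before`/`after` the
disturbance), a focal-individual identifier, focal and partner species,
an ordinal proximity category, an outcome, and a chase distance in
metres when the outcome is a chase. The semantics the code enforces:

* an encounter exists only within 1 m, so proximity is one of four
  25 cm bins coded 1–4 (1 = 0–24 cm ... 4 = 75–100 cm), recorded as the
  smallest distance observed;
* outcomes are `passive`, `signal` (aggression resolved by display
  alone) or `chase`; a chase distance is present if and only if the
  outcome is a chase;
* focal identity is only unique within reef × period. The field
  protocol (a U-shaped search, one member of each mated pair) minimizes
  re-sampling an individual within a survey but cannot link identities
  across periods, so the analysis never treats before/after as paired
  and every per-individual computation keys on region/reef/period/id.

Species labels are canonicalized by trimming/collapsing whitespace and
case-folding; no synonym resolution is attempted. Averaging the ordinal
codes is defensible here because the bins have equal 25 cm widths, so
the codes form an interval scale.

### Inclusion rules

`apply_pair_filter()` keeps a species pair only with at least 5
encounters across at least 5 distinct focal individuals (both
thresholds configurable), and emits an audit table of every pair's
counts. Two unstated corners had to be decided:

* *Which individuals count?* Only focal individuals — the only
  identified party in the data.
* *Within period or pooled?* The default pools across periods, with
  `filter_by_period = TRUE` as the switch; pooling is the weaker
  assumption and keeps the pair set identical in both periods.

`build_matched_subset()` further restricts to species passing the
filter in at least one conspecific *and* one heterospecific pair, so a
class contrast cannot be driven by a wider species pool on one side.
Because deleting records changes pair counts, a single
filter-and-restrict pass is not idempotent; the implementation iterates
to a fixed point, which is.

Regions that escaped the disturbance contribute no after contrast;
`exclude_after_period()` removes their after-period records only.
Chase distances at or beyond 10 m are recorded as exactly 10 m
(`cap_chase_distance()`): rare very long chases would otherwise
dominate dispersion statistics. The cap is a single boundary value, is
configurable, and is applied before any chase statistic, including the
per-pair CVs (a config switch, `cap_m`, governs the boundary).

## Resampling inference

### Rank test on individual means

Per-individual mean proximities (one value per individual × class ×
period) remove the repeated-measures dependence within individuals.
The two classes are then compared with a rank test: with ranks
\(r_i\) (mid-ranks for ties) of the pooled sample and \(W\) the rank
sum of the first group,

\[ Z = \frac{W - n_x \bar r}{\sqrt{\tfrac{n_x n_y}{N(N-1)}
      \sum_i (r_i - \bar r)^2}}, \]

whose denominator is the exact tie-corrected permutation standard
deviation. The p-value is Monte-Carlo: the proportion of random label
permutations whose \(|Z|\) reaches the observed one, **counting the
observed arrangement** (so \(p \ge 1/(B+1)\) and the test is exact-in-
expectation at any B). The default is 10,000 permutations; every report
records the count and seed. Positive \(Z\) means the first group (the
heterospecific class, in the pipeline) carries larger ranks, i.e.
greater distances. If all observations are tied the statistic is
defined as 0 with p = 1.

### Permutation χ² with a one-per-individual bootstrap

The signal/chase split is cross-tabulated against a 2-level label
(class or period) and summarized by Pearson's
\(X^2 = \sum (O-E)^2/E\) without continuity correction; a table with a
zero margin carries no information and is flagged, with the statistic
defined as 0. The permutation null holds both margins fixed, which is
exactly the distribution obtained by permuting labels; it is sampled
with `stats::r2dtable()` (Patefield's algorithm), and the p-value is
upper-tail with the observed table counted.

Because individuals contribute several encounters, the test is wrapped
in a bootstrap (`bootstrap_one_per_individual()`): each of B = 1000
replicates keeps exactly one uniformly chosen encounter per focal
individual, recomputes the test, and the report gives means and
2.5/97.5 percentile intervals of statistic and p across replicates. The
percentile interval is used because nothing sharper is warranted for a
summary of replicate spread; a "±" display is half its width.
Replicates where a label level disappears under subsampling are flagged
NA and dropped from aggregation (their count is reported).

One numerical property worth knowing: the permutation distribution of
\(X^2\) on a 2×2 table is discrete, so the test is conservative on
small tables — its exact size at nominal 0.05 is about 0.027 at 60
encounters and 0.040 at 200 (computable from the hypergeometric null).
The calibration checks in the test suite therefore use 200-encounter
tables, where attainable p-values are dense; on small field tables the
test errs on the safe side, as any exact conditional test does.

### Equality of coefficients of variation

Chase-distance variability is compared through the CV. Reported CVs use
the \(n-1\) sample formula \(s/\bar x\); the test machinery uses MLE
(\(n\)-denominator) quantities internally — the two conventions are
documented and tested separately.

The test works under independent normal models
\(X_{ij} \sim N(\mu_i, \sigma_i^2)\) with H₀: \(\sigma_i/\mu_i = \tau\)
for all groups. For fixed \(\tau\) the group mean has a closed-form
profile solution: setting the score to zero gives
\(n\tau^2\mu^2 + S\mu - Q = 0\) with \(S=\sum x\), \(Q=\sum x^2\),
whose positive root (evaluated in the cancellation-free form
\(2Q/(S+\sqrt{S^2+4n\tau^2 Q})\)) is the profiled mean. The common
\(\tau\) is then a one-dimensional `optimize()` over a bracket spanning
the per-group MLE CVs (argument tolerance 1e−9, giving log-likelihood
agreement far below 1e−6; a dense grid-search oracle in the test suite
confirms the optimum). The signed likelihood-ratio statistic is
\(2(\ell_1-\ell_0) \sim \chi^2_{k-1}\).

The small-sample *modified* statistic rescales the SLRT so its null
mean matches the \(\chi^2_{k-1}\) mean, with the scale estimated by
parametric bootstrap at the constrained MLE (default 1000 replicates,
seeded). This Bartlett-type mean correction is what makes the test
robust to small and unequal group sizes; the type-I calibration test
(normal groups with a common CV, n = 20 per group, 1000 simulations)
verifies the corrected test holds its size where the uncorrected SLRT
is anti-conservative. The correction washes out as groups grow, which
the suite checks at n = 20/200/2000. Simulated bootstrap samples may
have negative means when the common CV is large — the likelihood core
tolerates this (the profiled mean stays positive for any data), while
user-facing input still requires positive-mean groups.

The normal working model is applied to *capped* distances, although
capping (and the right skew of real chases) violates normality. This
mirrors how such field data are analysed in practice; the pipeline's
null-scenario checks show the test's behaviour under the log-normal +
cap generator remains calibrated at the sizes used, and the matched-
subset comparison is reported alongside as a robustness check.

## Comparative models

`patristic_distances()` computes the summed branch length between two
tips by accumulating root-to-tip paths and subtracting twice the depth
of the most recent common ancestor. Newick parsing is delegated to
`ape::read.tree()`; the distance computation itself is authored here
and cross-checked against `ape::cophenetic.phylo()` in the tests, with
the four-point condition spot-checked on quartets. Trees must carry
branch lengths on every edge.

The pair table (`build_pair_observations()`) has one row per
heterospecific pair — conspecific pairs are excluded since their
phylogenetic distance is identically zero and would swamp the
regression with structural zeros. Responses: mean proximity over the
pair's encounters; signal/chase counts over its aggressive encounters;
the CV of its capped chase distances when it has at least `min_chases`
(default 5, mirroring the global inclusion rule — the study-level rule
for this response is unstated, so the package extends the ≥ 5
convention and leaves it configurable). A pair lacking a response is
simply absent from that model, so the three models legitimately have
different n.

Continuous responses use OLS with an intercept on phylogenetic
distance + body-size difference; adjusted R² is stored raw (it may be
negative) and floored at zero only in the printed summary. Signalling
uses an aggregated binomial GLM — `cbind(n_signal, n_chase)` with logit
link — because per-pair proportions with unequal denominators are
exactly what the binomial likelihood weights correctly. Predictive
ability is McFadden's \(R^2 = 1 - \ell/\ell_0\) against the
intercept-only fit (exactly 0 for the null model by construction).
Near-collinear predictors (condition number > 1e8) and fitted
probabilities pinned at 0/1 (separation) are flagged in the result.

## The synthetic generator

`generate_dataset()` emulates the sampling design: regions × reefs ×
two periods × focal individuals per species, a Poisson number of
encounters per individual, a Bernoulli conspecific/heterospecific
partner mix, and behavioural parameters organized as 2×2
period-by-class matrices. Proximity is a latent normal approach
distance truncated to (0, 100] cm and cut at 25/50/75 cm — the latent
threshold construction matches how the field bins arise. Aggression
probability follows a logistic in proximity (closer → more likely),
signalling-given-aggression is a per-cell probability, and chase
distances are log-normal with per-cell mean and CV (right-skewed and
positive, which is why rare long chases occur and a cap matters; the
family is a generator choice, applied uncapped — capping belongs to the
analysis).

`reference_scenario()` is the reference configuration. Its planted
truths reproduce the directions and magnitudes characteristic of the
studied system: conspecific latent approach 32 cm in both periods
versus heterospecific 55 cm before narrowing to 45 cm after;
signalling-given-aggression 0.07 (con) vs 0.28 (het) before, dropping
to 0.05/0.08 after; conspecific chases with mean 3.46 m and CV 1.0 in
both periods versus heterospecific mean 1.35 m, CV 1.4 before and
1.67 m, CV 1.0 after; one of five regions skips the disturbance (its
after records are generated from before-parameters and excluded from
the after contrasts); and an after-period encounter rate of 0.72×.
At `size = 1` this yields roughly 2300 before and 1300 usable after
encounters across 12 species — the scale at which the package's
direction-recovery checks run. Phylogeny (pure-birth via
`ape::rphylo()`) and body size (log-normal around 18 cm, the
characteristic scale of these fishes) influence nothing, so the
comparative models should and do find ≈ 0 explanatory power.

What the generator deliberately does **not** emulate: territory
geometry and spatial aggregation at food patches, observer effects,
repeated-pair dynamics beyond multiple encounters per individual,
cross-period individual identity, and any dependence of behaviour on
phylogeny or size. Passing tests therefore show the *inference
machinery* is correct and calibrated under the design's dependence
structure — not that real reef data satisfy the generator's
distributional assumptions.

## Determinism and problem sizes

Every random procedure takes an explicit seed; the pipeline derives
child seeds from one master seed and logs them, and temporarily swaps
the RNG state so callers' streams are never clobbered. Identical
configuration + master seed gives a byte-identical `report.json`.

The shipped checks use problem sizes chosen to make the statistical
point at interactive cost: 1000 null simulations per calibration check
(the 99% binomial band around 0.05 is ±0.018 there), 100 seeds for the
direction-recovery check at study scale with reduced resample counts
(999 permutations, B = 25 — directions depend on point estimates, not
on resampling precision), and full enumeration oracles on instances of
at most 10 observations. Production settings (10,000 permutations,
B = 1000, 1000 correction replicates) are the defaults users get.

## Known limitations

* The CV test's normal working model is a pragmatic approximation for
  capped, skewed chase distances; its calibration under the generator
  is verified, but strongly non-normal real data may deserve a
  sensitivity check with the cap varied.
* The matched-subset iteration can discard species aggressively in
  small datasets; the audit table shows exactly which pairs fell where.
* Permutation χ² p-values are conservative on small tables
  (discreteness), and the one-per-individual bootstrap shrinks tables
  further; interval widths in the report make this visible.
* No phylogenetic regression correction (e.g. PGLS) is applied in the
  comparative models — they are ordinary regressions on pair-level
  summaries, and pairs sharing a species are not independent.
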