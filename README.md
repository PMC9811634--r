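# agonistics

Statistical analysis of agonistic encounters in communities of
territorial reef fishes, built around a natural experiment: behaviour
observed before and after a mass resource-depletion event (a coral
die-off, for corallivorous butterflyfishes). The package is aimed at
behavioural ecologists who record focal-individual encounter data —
who met whom, how close they came, and whether the contest ended
passively, with a ritualized signal, or with a chase — and want
resampling-based inference that respects the pseudoreplication inherent
in repeated observations of the same individuals.

The analysis asks four questions about competitor recognition:

1. **Proximity.** Do individuals let conspecifics approach more closely
   than heterospecifics? Proximity is recorded in four ordinal 25 cm
   bins within 1 m; per-individual means are compared with a
   Mann–Whitney-type rank test whose reference distribution is a
   Monte-Carlo sample of label permutations. The reported statistic is
   the standardized linear rank statistic
   *Z* = (W − E₀[W]) / √Var₀(W), with mid-ranks for ties and the
   tie-corrected permutation variance.
2. **Signalling.** Are contests more often resolved by signalling
   (rather than escalating to a chase) between conspecifics? The
   signal/chase split is compared with permutation χ² tests, wrapped in
   a bootstrap that resamples **one encounter per focal individual**
   (B = 1000), reporting mean X², mean p and 95% percentile intervals
   across replicates.
3. **Attack variability.** Are chase distances (capped at 10 m) more
   variable between heterospecifics? Variability is the coefficient of
   variation CV = s/x̄, and CV equality across groups is tested with a
   signed likelihood-ratio test under a normal working model
   (2·(ℓ₁ − ℓ₀) ~ χ²ₖ₋₁) plus a small-sample modified version whose
   Bartlett-type correction is estimated by parametric bootstrap.
4. **Comparative predictors.** Does phylogenetic distance (patristic,
   i.e. summed branch lengths between two tips) or body-size difference
   predict pairwise proximity, signalling proportion, or chase-distance
   CV? OLS for the continuous responses (adjusted R², overall F
   p-value); an aggregated binomial GLM with logit link for signalling,
   scored by McFadden's pseudo-R² = 1 − ℓ/ℓ₀.

Species pairs enter the analysis only with ≥ 5 encounters across ≥ 5
focal individuals, and a stricter "matched" subset keeps species that
clear that bar in both conspecific and heterospecific encounters. A
synthetic data generator (`generate_dataset()`, `reference_scenario()`)
simulates the whole design — regions, reefs, two periods, focal
individuals, ordinal proximity, outcomes, right-skewed chase distances,
a pure-birth phylogeny and a trait table — with every effect size known,
so calibration and recovery are testable without field data.

## Worked example

```r
library(agonistics)

cfg <- run_config(scenario = reference_scenario(seed = 42),
                  n_permutations = 999, n_bootstrap = 100,
                  mslr_nr = 200, seed = 42)
report <- run_agonistic_analysis(cfg)
summary(report)
```

```
== Proximity (per-individual means, permutation rank test) ==
before: con 1.995 vs het 2.652  (Z = 14.387, p = 0.001, n = 473/637)
after: con 1.959 vs het 2.338  (Z = 7.003, p = 0.001, n = 306/440)

== Signalling (bootstrap x permutation chi-squared) ==
class_before: X2 = 31.883 [21.297, 43.892], p = 0.001 [0.001, 0.001]
class_after: X2 = 0.567 [0.005, 2.097], p = 0.632 [0.193, 1.000]
period_conspecific: X2 = 0.300 [0.001, 0.926], p = 0.700 [0.370, 1.000]
period_heterospecific: X2 = 40.622 [34.143, 47.822], p = 0.001 [0.001, 0.001]

== Chase-distance variability (CV equality) ==
min5/before: CVs conspecific 0.768, heterospecific 1.125; MSLR = 20.746, p = 0.000
min5/after: CVs conspecific 0.817, heterospecific 0.955; MSLR = 2.021, p = 0.155
...

== Comparative models (phylo distance + size difference) ==
proximity: adj R^2 = 0.000, p = 0.788, n = 66
signalling: McFadden R^2 = 0.001, n = 66
chase_cv: adj R^2 = 0.000, p = 0.469, n = 66
```

Reading this: conspecifics tolerate closer approach in both periods
(individual mean proximity 1.99 vs 2.65 bins before; positive *Z* means
the heterospecific group carries the larger ranks). Heterospecific
contests are resolved by signalling far more often than conspecific
ones before the disturbance (X² ≈ 32) but not after (X² ≈ 0.6), and the
change is confined to heterospecifics (period contrast X² ≈ 41 vs 0.3).
Heterospecific chase distances are more variable before (CV 1.13 vs
0.77) with the gap closing afterwards. The comparative models find no
phylogenetic or body-size signal — as expected, since this scenario
plants none. Every number above equals the corresponding standalone
function applied to the same intermediate data (`mwu_permutation_test`,
`chisq_permutation_test`, `mslr_test`, `fit_linear_model`,
`fit_binomial_glm`), which the test suite asserts.

To analyse real field data, pass files instead of a scenario:

```r
cfg <- run_config(paths = list(encounters = "encounters.csv",
                               tree = "phylogeny.nwk",
                               traits = "traits.csv"),
                  excluded_after_regions = "philippines",
                  seed = 1)
report <- run_agonistic_analysis(cfg)
write_run_report(report, "out/")   # deterministic report.json + audit.csv
```

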