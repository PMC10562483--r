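---
title: "CHAMP: scoring river-barrier habitat alteration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CHAMP: scoring river-barrier habitat alteration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(champ)
```

## The model

Backwater impoundments upstream of artificial barriers turn flowing-river
habitat into pond-like habitat. CHAMP (Conceptual Habitat Alteration Model
for Ponding) quantifies that change relative to the fish community a river
reach is expected to support, rather than describing the altered state in
detail. It rests on three score layers:

* **HP** — how important each of 21 free-flowing habitat criteria (flow
  velocity, depth, substrate, cover, physico-chemistry, vegetation, bank
  structure, floodplain access, continuity, flow stability) is for each of
  11 habitat-use guilds; 0 / 0.5 / 1.
* **HA** — how impoundment by each of six barrier types (dam, weir, sluice,
  culvert, ford, ramp) changes the area supporting each criterion;
  0 (major reduction) to 2 (major increase) in steps of 0.5.
* **AHS = HP × HA** — altered habitat suitability per guild, criterion and
  barrier type.

Summing AHS over criteria and normalising by the guild's total preference
(its ponding sensitivity index, PSI = ΣHP) gives the remaining riverine
habitat proportion

$$RHp_{i,b} = \frac{\sum_j HP_{i,j}\, HA_{b,j}}{\sum_j HP_{i,j}} \in [0, 2],$$

1 meaning no change and values above 1 a net gain (limnophilic and
generalist guilds can profit from ponding). Weighting RHp by the expected
guild proportions $GP_i$ of a macrohabitat type gives the community-level
$wRHp = \sum_i GP_i\, RHp_{i,b}$ (0–200%), and weighting PSI the same way,
relative to the maximum attainable suitability (the criterion count, 21 by
default), gives the community's sensitivity to impoundment in percent.

```{r}
hp <- read_hp(system.file("extdata", "hp_default.csv", package = "champ"))
ha <- read_ha(system.file("extdata", "ha_default.csv", package = "champ"))
round(100 * unclass(rhp_table(hp, ha)), 1)[1:4, ]
```

### Categorical bins

wRHp severities follow the printed integer-styled bins, extended half-open
so they cover the real line: severe ≤ 25 < major ≤ 50 < substantial ≤ 75
< moderate ≤ 90 < low. Sensitivity classes read "between 45% and 55%" as
the closed interval [45, 55] for *moderate*; both boundary sets are plain
function arguments and can be overridden.

## Expected communities and macrohabitat types

Expected guild proportions for a macrohabitat type come from a target-
fish-community procedure: `tfc_expected_proportions()` draws `n = 10`
reference sites of the type (seeded, sampling frame sorted by site id so the
result is order-invariant), sums observed guild proportions, ranks guilds by
the sum, and normalises reciprocal ranks 1/r to sum 1. Ties take the average
rank — this keeps the output invariant under guild reordering — and guilds
absent from the draw are excluded from ranking and receive 0.

Typing itself is a two-step clustering (`two_step_typology()`): Gower
dissimilarity on the physical attributes (Strahler order, catchment area,
geology, climate zone — slope and altitude are carried descriptively but
excluded from the feature set, where they degrade discrimination), PAM
medoid clustering, then the physical-cluster label is appended to the guild
proportions (one-hot by default; a single numeric label column is the
alternative encoding) and the mixed data are re-clustered under city-block
distance. Cluster counts are chosen by average silhouette width
(`choose_k()` returns the full table so a scree inspection can override the
argmax). Typology quality is checked with ANOSIM; `champ_anosim()`
enumerates all distinct label arrangements exactly when there are no more
of them than the permutation budget, so small-sample p-values are exact.

The attribute → type classifier is a CART tree (`rpart`, Gini impurity,
cost-complexity pruning at `cp`, default 0.01) reported with training
Cohen's kappa. The fitted tree serialises to a plain JSON node list
(`classifier_to_json()`); the hand-written walker (`predict_type_json()`)
routes numeric values ≤ threshold to the recorded side — thresholds are
midpoints between observed values, so the convention cannot disagree with
the fitted tree on data — and rejects unseen categorical levels. Missing
geology can be filled from the nearest upstream segment when a topology is
supplied (`fill_geology()`), else it is flagged.

## Continental extrapolation

A barrier's impoundment length is approximated by height over slope,
h (m) / s (‰) = km. Records with zero slope or missing height are excluded
and tallied, never turned into infinities. Remaining habitat inside the
impounded reach is L × wRHp; alteration is the difference, kept negative
when wRHp > 1. Observed (calculated) per-type sums are scaled up for the
two observation gaps — only a fraction p of recorded barriers carry a
height, and a fraction err of real barriers is absent from the inventory —
by 1/((1 − err) p), per type, summed over the impoundment-forming types
(dams, weirs, sluices by default; the small types can be enabled when
correction factors exist for them). This ratio correction is unbiased when
height missingness is independent of barrier size; the generator's
`size_biased` option exists precisely to exercise the dependent case, which
is biased and documented as such.

Catchment-level summaries use the standard median of per-barrier wRHp.
Restoration ranking places each barrier at (1 − wRHp, upstream length
blocked / max) and sorts by Euclidean distance from the origin, ties broken
by barrier id.

## The synthetic generators

Restricted source data (the intercalibration survey database and the
continental barrier atlas) are emulated, not shipped. The generators
(`sim_config()`, `generate_profiles()`, `generate_sites()`,
`generate_barriers()`) reproduce the *structure* the pipeline assumes:

* 15 macrohabitat types over 11 guilds, each type's expected profile a
  Dirichlet draw anchored on a rotating dominant guild, redrawn until all
  pairwise city-block separations reach 0.5;
* site guild proportions Dirichlet-concentrated (default 60) around the
  type profile, physical attributes from type-conditional distributions;
* barrier types at frequencies dominated by weirs and the small structures;
  log-normal heights with medians 8 m (dams) > 1.5 m (weirs) > 1.2 m
  (sluices) > the small types, a lowland/mountain log-normal slope mixture
  (medians 1.5‰ and 20‰, 30% mountain);
* height-information proportions and underreporting errors defaulting to
  the published inventory diagnostics for dams (p = 0.483, err = 0.157),
  weirs (0.320, 0.582) and sluices (0.595, 0.720), with illustrative values
  for culverts, fords and ramps.

The paper behind the model gives no distributional forms for heights or
slopes, so these defaults are labelled illustrative and are all
overridable; they were fixed once, on field plausibility, before any
testing. What the synthetic data do **not** emulate: spatial river-network
topology, regional species pools, survey-method noise, or any dependence
between barrier density and macrohabitat. Recovery results on synthetic
data therefore demonstrate the pipeline's correctness, not the realism of
any particular European typology.

## Numerical conventions

* RHp and wRHp are fractions internally and percentages only at I/O
  boundaries, avoiding double scaling between the score algebra and the
  kilometre accounting.
* All stochastic steps (profile/site/barrier generation, TFC draws,
  sampled ANOSIM permutations) take explicit integer seeds and restore the
  caller's RNG state. PAM itself is deterministic (BUILD + SWAP).
* Zero-range numeric variables are dropped from Gower dissimilarities with
  a warning; constant data would otherwise contribute 0/0.
* Reports round kilometres to integers and percentages to one decimal;
  internal arithmetic is unrounded.

## Problem sizes used in the checks

The shipped checks run the typology recovery on 5 well-separated types ×
20 sites, exact ANOSIM enumeration on up to 7 points, exhaustive medoid
search on up to 8, and the estimator-recovery study on 20 replicates of a
1,500-barrier population — sizes at which the independent oracles
(exhaustive enumeration, brute-force loops) are themselves cheap to run.
The continental worked example uses the published per-type summary inputs
shipped in `inst/extdata/table2_inputs.csv`.

## Known limitations

Only upstream (ponding) alteration of adult/rearing/growth habitat is
modelled — no downstream effects, passability, spawning or larval niches.
The default HP/HA matrices shipped here are a synthetic fixture consistent
with the published worked score examples, suitable for testing and as a
drop-in template; substantive applications should supply expert-scored
matrices. The underreporting correction assumes missingness independent of
barrier size; national registers that record only large barriers violate
this and bias totals downward.
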