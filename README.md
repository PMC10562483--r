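# champ

Impoundments — the backwater ponds upstream of dams, weirs, sluices,
culverts, fords and ramps — convert flowing-river habitat into still-water
habitat. How much that matters depends on which fish community a river
reach is expected to support: a rheophilic mountain community loses almost
everything, a limnophilic lowland community may even gain. `champ`
implements the Conceptual Habitat Alteration Model for Ponding for
freshwater ecologists and river-basin managers who need to score, map and
prioritise barrier impacts at anything from a single weir to a continental
inventory.

## The model in brief

For guild *i*, habitat criterion *j* and barrier type *b*:

* `HP[i,j] ∈ {0, 0.5, 1}` — importance of the criterion for the guild;
* `HA[b,j] ∈ {0, 0.5, 1, 1.5, 2}` — change of the criterion under
  impoundment (0 major reduction … 2 major increase);
* `AHS = HP × HA` — altered habitat suitability;
* `PSI_i = Σ_j HP[i,j]` — ponding sensitivity index of the guild;
* `RHp[i,b] = Σ_j HP[i,j]·HA[b,j] / PSI_i ∈ [0, 2]` — remaining riverine
  habitat proportion (1 = unchanged);
* `wRHp[b] = Σ_i GP_i·RHp[i,b]` — community-weighted remaining habitat,
  where `GP_i` are the expected guild proportions of the reach's
  macrohabitat type (0–200 %);
* macrohabitat sensitivity `= 100·Σ_i PSI_i·GP_i / 21`.

Expected guild proportions come from a reciprocal-rank target-fish-community
procedure over reference sites; macrohabitat types from a two-step PAM
clustering (Gower on physical attributes, city-block on guild proportions +
physical cluster) validated by ANOSIM and carried to unsurveyed reaches by
a CART attribute classifier. Continental habitat-alteration totals follow
from per-barrier impoundment lengths `h/s` (height over slope), scaled per
type by `1/((1 − Err_b)·p_b)` to correct for barriers without height
records (`p_b`) and barriers missing from inventories entirely (`Err_b`).

## Worked example

```r
library(champ)
hp <- read_hp(system.file("extdata", "hp_default.csv", package = "champ"))
ha <- read_ha(system.file("extdata", "ha_default.csv", package = "champ"))
tab <- rhp_table(hp, ha)
round(100 * unclass(tab)[c("RH_INT", "LB_MT", "GEN"), c("dam", "culvert", "ford")], 1)
#>          dam culvert  ford
#> RH_INT  30.8    82.7 100.0
#> LB_MT  108.8    94.1  97.1
#> GEN    118.2    90.9  95.5
```

A dam leaves the intolerant highly rheophilic guild (`RH_INT`) only 31 % of
its habitat, while limnophilic benthic fish (`LB_MT`) and generalists
(`GEN`) come out ahead (>100 %); a ford changes almost nothing. Weighting
by a macrohabitat's expected community and classifying:

```r
profiles <- read_profiles(system.file("extdata", "profiles_synthetic.csv",
                                      package = "champ"))
compute_wrhp(tab, profiles$t1)
#>   barrier_type wRHp_percent    severity
#> 1          dam     59.19316 substantial
#> 2         weir     70.16717 substantial
#> 3       sluice     77.25951    moderate
#> 4      culvert     87.04382    moderate
#> 5         ford     98.65172         low
#> 6         ramp    101.69136         low
```

In this (synthetic) macrohabitat a dam leaves 59 % of community-weighted
habitat — substantial alteration — while a ramp is a slight net gain.
Scaling one observed inventory total up for missing heights and
underreporting (dams: 48.3 % of records with height, 15.7 % underreported):

```r
correct_type_totals(22180, 8591, 28913, list(p = 0.483, err = 0.157))
#>   est_impoundment_km est_remaining_km est_alteration_km projected_count
#>                54474            21099             33374           71010
```

i.e. an estimated 54,474 km of impounded river, of which 33,374 km no
longer provides the expected free-flowing habitat, across a projected
71,010 dams.

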