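# citrusvol

Decision support for adjusting the spray **mix volume rate (L/ha)** of plant
protection product (PPP) applications in citrus orchards sprayed with
airblast equipment, following the CitrusVol methodology.

PPP labels for citrus are usually expressed as a mix concentration (%) or a
maximum dose per hectare of ground, which ignores how much canopy there
actually is to treat. `citrusvol` instead works back from the minimum liquid
deposit per leaf area needed for maximum control efficacy:

```
V_R = D · S_W · N · f_lab-field / f_E          (L/ha)

S_W = 2 · S · f_target                          leaf surface to wet, m²/tree
S   = LAD · VT                                  one-sided leaf area, m²/tree
VT₁ = (π/6) · h · Ø_across · Ø_along            ellipsoid canopy volume, m³/tree
N   = 10000 / (sp_tree · sp_row)                trees/ha
```

where `D` is the minimum deposit (3.41 µL/cm² for contact products, 4.72 for
suffocating products), `f_target` the canopy fraction to wet for the pest
class (1 internal, 0.75 intermediate, 0.49 external), `LAD` the leaf area
density from the cultivar-density × pruning lookup (2.5–5.0 m²/m³),
`f_lab-field = 0.8` the laboratory-to-field survival correction and
`f_E = 0.6` the airblast application efficiency. For orchards with gaps
between trees along the row (`Ø_along < sp_tree`) a second rate based on
`VT₂ = (π/6)·h·Ø_across·sp_tree` is reported for sprayers without
canopy-detection technology, together with the volume a detection sprayer
would save.

The package also provides:

* `quadrant_lad()` / `orchard_lad()` — the cube-sampling field estimator of
  leaf area density (70 cm cube, subsample specific leaf area);
* `mix_reduction()`, `ppp_savings()`, `tanks_needed()`,
  `refill_time_savings()`, `summarize_trials()` — savings arithmetic for
  paired conventional (Vc) / adjusted (Va) applications;
* `trv()`, `lwa()`, `ucr_units()`, `compare_methods()` — the classical Tree
  Row Volume, Leaf Wall Area and Unit Canopy Row dose expressions as
  comparators;
* `load_fixture("T3")` … `"T6"` — the bundled field-evaluation tables (seven
  commercial clementine orchards, fourteen paired applications);
* a command line (`inst/cli/citrusvol.R`) with subcommands `recommend`,
  `lad-estimate`, `evaluate-trials`, `compare-methods`, `validate-db`.

## Worked example

A normally pruned Clemenules orchard (medium-density cultivar) on a
6.8 m × 5 m frame, canopies 2.15 m high, 3.39 m across the row and 3.34 m
along it, treated against California red scale with chlorpyrifos:

```r
library(citrusvol)
geom <- orchard_geometry(h = 2.15, d_across = 3.39, d_along = 3.34,
                         sp_tree = 5, sp_row = 6.8)
recommend(geom, "Clemenules", "normal",
          target = "California red scale", product = "chlorpyrifos")
#> Volume rate recommendation
#>   target:  California red scale (internal, f_target = 1)
#>   product: chlorpyrifos (contact, D = 3.41 uL/cm2)
#>   LAD = 3.7 m2/m3, N = 294.12 trees/ha, VT1 = 12.75 m3/tree
#>   Recommended volume rate (canopy-detection sprayer): 1261 L/ha
#>   Recommended volume rate (conventional sprayer):     1888 L/ha
#>   Volume saved with canopy detection: 33.2%
#>   ! Check the technical data sheet of the product...
```

Reading the output: the 12.75 m³ ellipsoid canopy carries
3.7 × 12.75 ≈ 47 m² of leaf per tree, of which both sides must be wetted for
an internal pest (f_target = 1). Because the canopies (3.34 m) do not span
the 5 m tree spacing, a conventional sprayer also treats the gaps, so two
rates are given; a sprayer that closes its nozzles over the gaps would spray
1 − 3.34/5 ≈ 33% less. The advisory reminds the user that label-imposed
volume or dose maxima are outside the model.

Side by side with the classical dose expressions for the same orchard:

```r
compare_methods(geom, lad = 3.7,
                target = "California red scale", product = "chlorpyrifos")
#>   method    crop_metric units                    volume_rate
#> 1 TRV            10718. m3 foliage/ha                  1008.
#> 2 LWA             6324. m2 wall/ha                       NA
#> 3 UCR              107. UCR units/ha                     NA
#> 4 CitrusVol       3749. m3 canopy/ha (ellipsoid)       1888.
```

The TRV box (10,718 m³/ha) is nearly three times the ellipsoid canopy volume
(3,749 m³/ha) for the same trees — the coarseness the deposit-based model is
designed to avoid.

Same calculation from the shell:

```sh
Rscript inst/cli/citrusvol.R recommend \
  --height 2.15 --d-across 3.39 --d-along 3.34 --sp-tree 5 --sp-row 6.8 \
  --cultivar-group medium --pruning normal \
  --target "California red scale" --product chlorpyrifos
```

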