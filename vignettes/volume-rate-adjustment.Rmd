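---
title: "Adjusting spray volume rates in citrus orchards: model and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting spray volume rates in citrus orchards: model and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citrusvol)
```

## The problem

Plant protection product (PPP) labels for citrus in the EU southern zone are
typically expressed as a concentration of the spray mix (%) or as a maximum
dose per hectare of ground. Neither expression reflects what actually drives
control efficacy in a three-dimensional crop: how much product ends up
deposited per unit of leaf area. Two orchards with the same ground area can
differ several-fold in leaf area, so a fixed L/ha rate simultaneously
overdoses small canopies and underdoses large ones.

`citrusvol` turns the problem around: it starts from the minimum liquid
deposit per leaf area known to give maximum control efficacy for a pest class
and product type, scales it up through the orchard's actual leaf area, and
corrects for how much of the sprayed liquid ever reaches the canopy. The
output is the mix volume rate (L/ha) to set on an airblast sprayer, given
that products are dosed as mix concentration.

## The model

The recommended volume rate is

$$ V_R = \frac{D \cdot S_W \cdot N \cdot f_{lab\text{-}field}}{f_E}, $$

with the leaf-surface chain

$$ S_W = 2\,S\,f_{target}, \qquad S = LAD \cdot VT, \qquad
   VT_1 = \tfrac{\pi}{6}\, h \, \varnothing_{across} \, \varnothing_{along}, \qquad
   N = \frac{10000}{sp_{tree}\, sp_{row}}. $$

* **D** (µL/cm²) is the minimum deposit for maximum efficacy. Two reference
  values are used, on the safety side across pest generations: 3.41 for
  contact products (organophosphate reference) and 4.72 for suffocating
  products (mineral oil reference). The registry maps active ingredients to
  one of these two classes; ingredients without an efficacy–deposition model
  of their own are classed as contact in the shipped data, and the class can
  be overridden by passing `"contact"`/`"suffocating"` directly.
* **S_W** (m² leaf/tree) is the surface to wet: both sides of the leaves
  (factor 2) and only the canopy fraction the target requires. Internal
  targets (armored scales, mites, mealybugs...) need the whole canopy
  (`f_target` = 1), intermediate ones (thrips, aphids, leafminers...)
  two-thirds (`f_target` = 0.75), external ones (Mediterranean fruit fly)
  one-third (`f_target` = 0.49). These fractions are authoritative lookup
  constants derived for an ellipsoidal canopy; the package deliberately does
  not re-derive them geometrically (naive ellipsoid shell-volume fractions do
  not reproduce 0.49, so the published constants are shipped as data).
* **VT** (m³/tree) is the apparent canopy volume of an ellipsoid with axes
  `h` (canopy height, measured from the *bottom of the canopy*, not from the
  ground), and the two canopy diameters. The unit bridge in the volume
  equation is 1 µL/cm² × 1 m² = 0.01 L.
* **f_lab-field = 0.8** discounts the laboratory deposit because field
  survival of pests is lower than in the laboratory.
* **f_E = 0.6** is the application efficiency of a conventional airblast
  sprayer in Mediterranean citrus (about half the spray reaches the canopy,
  plus roughly 20% improvement from the adjuvant normally present in the
  mix). Both constants are overridable through `dose_constants()` but default
  to the values above.

### Gapped rows: the two-case recommendation

When the canopy diameter along the row is at least the tree spacing the rows
form a hedge and the ellipsoid volume `VT1` describes what the sprayer
treats. When `d_along < sp_tree` there are gaps between trees; a sprayer
*without* canopy-detection technology keeps its nozzles open across the gaps,
effectively treating the larger volume
`VT2 = (π/6) h · d_across · sp_tree`. `recommend()` then reports both
`v_r1` (detection sprayer) and `v_r2` (conventional sprayer) plus the saving
a detection sprayer would achieve. Because the two volumes share every factor
except the third axis, that saving collapses to the closed form
`100·(1 − d_along/sp_tree)` %, which the test suite uses as an independent
oracle on randomly generated orchards. The boundary `d_along = sp_tree` is
assigned to case 1, following the "equal or larger" convention.

Recommendations are based on biological efficacy only, so every result
carries the advisory to check the product's technical data sheet for
label-imposed volume or dose maxima; targets with special handling (trunk
application for Phytophthora foot rot, bait-only products for medfly, no
authorized product for cottony cushion scale) add their own messages. The
messages are stored as identifiers and rendered to English text by
`warning_messages()`, keeping the data files localizable.

## Leaf area density

`LAD` (m² leaf/m³ canopy) comes from a 3 × 3 lookup: cultivar density group
(low — satsumas, lemons; medium — clementines, navels, some hybrids; high —
dense hybrids like Fortune) × pruning level (severe, normal, without
pruning), with values from 2.5 to 5.0. Both margins are strictly monotone and
the loaders re-assert this on every load, so a user-edited database that
breaks the ordering is rejected. No default is offered: the caller must pick
a group (or a registered cultivar name) and a pruning level, mirroring the
forced choice in the original tool's interface.

The field protocol behind those values is also implemented (`quadrant_lad()`,
`orchard_lad()`): a 70 cm cube (0.343 m³) is set in each canopy quadrant, all
leaves inside are collected and weighed, and a weighed subsample is scanned
for area, giving LAD as (g leaf/m³) × (cm² leaf/g) × 10⁻⁴. Quadrants are
averaged within each repetition (tree) first and repetitions averaged second;
for the balanced designs the protocol prescribes this equals the grand mean,
and balance is checked with a warning otherwise. The standard error is that
of the repetition means. The quadrant layout (2 heights × 4 sectors) is
carried as identifiers but not geometrically enforced, since the estimator
does not depend on it.

## Field-evaluation arithmetic

`summarize_trials()` reproduces the savings accounting used when the method
was evaluated in seven commercial clementine orchards (14 paired
applications, bundled as fixtures `T3`–`T6`):

* mix reduction `100·(Vc − Va)/Vc`;
* product savings `(concentration/100)·(Vc − Va)`, valid because citrus
  labels in Spain express dose as mix concentration;
* tank fills as the ceiling of total volume over tank capacity, taken over
  the *whole* sprayed area — the only convention that reproduces every
  published refill-time cell (per-hectare counts scaled by area cannot
  produce 0.67 h/ha alongside 7.33 h/10 ha) — and refill time saved at
  40 min per fill.

Two quirks of the published trial log are handled explicitly rather than
patched. First, two rows report reductions inconsistent with their own
volumes (a 3318→1628 L/ha application reported as 20.81% where the volumes
give 50.93%, and 22.28% where they give 22.99%); `summarize_trials()` keeps
the reported column, recomputes from the volumes, and flags the
contradictions in a `discrepancy` column. The trial-wide mean of the reported
column is 31.46%, of the recomputed reductions 33.66%; both are returned.
Second, one application carries different dates in different source tables
(13 vs 16 June); each fixture preserves its own table verbatim and the tank
fixture carries its own volume columns so nothing joins across the
inconsistent key.

A deliberate consequence of the ceiling convention: refill-time savings are
*not* monotone in area. Spraying 3 ha at 550 L/ha with a 1000 L tank needs
two fills against two for 500 L/ha (zero saved), while 2 ha needs two against
one (one fill saved). The tests pin the property that actually holds — saved
fills stay within one tank of the continuous difference `(Vc−Va)·area/capacity`
and are never negative.

## Comparators

`trv()`, `lwa()` and `ucr_units()` implement the classical dose-expression
descriptors for the same geometry: Tree Row Volume (rectangular-box rows,
`h·d_across·10000/sp_row` m³/ha, default optimum 0.094 L/m³ from the classic
apple calibration), Leaf Wall Area (vertical wall, two faces by default with
a `sides = 1` switch, since the concept is defined verbally rather than by a
canonical equation), and Unit Canopy Row (100 m³ canopy units per hectare).
They exist to make the contrast visible: the TRV box always contains the
ellipsoid canopies it replaces (ratio `6·sp_tree/(π·d_along)`), and none of
the three sees leaf density, the pest, or the product. No citrus-specific
TRV constant is shipped; `rate_per_m3` is a user parameter.

## Numerical choices and validation scale

All arithmetic is closed-form and deterministic; no seeds, tolerances or
iterative solvers are involved. Planting density is kept as a real number
(frames rarely divide a hectare evenly). Volume rates are reported at full
precision and rounded only for display (nearest litre in the CLI). Input
validation rejects non-positive quantities, fractions outside (0, 1], and
canopy dimensions above 15 m; spacings are only required positive, so
degenerate wide-spacing unit cases remain expressible. Case selection at
`d_along = sp_tree` is exact comparison, which is safe because both branches
coincide there.

The regression suite recomputes the published evaluation end to end: all
seven canopy volumes to ±0.01 m³, the reduction and savings columns to their
printed precision, every refill-time cell at 1/10/100 ha to ±0.02 h
(print-rounding slack), and the full P1 pipeline against the volume rate
actually applied in that orchard (3255 L/ha), which it matches within 5% —
exact agreement is not expected because the published geometry is rounded to
centimetres while the original recommendation used unrounded field
measurements. Property tests run on randomly generated orchards (fixed
seeds, dozens of cases per property) for the scale laws, the sensor-savings
closed form, linearity of `V_R` in each factor, and deposit recovery by
algebraic inversion.

## Limitations

The canopy is a single mean ellipsoid: no row-end profile, no within-orchard
variability, no sensor-based reconstruction. The deposit references cover two
modes of action calibrated on California red scale; other ingredients borrow
the contact reference until efficacy–deposition models exist for them. The
savings arithmetic assumes the conventional and adjusted applications differ
only in volume rate. Label-imposed maxima are out of scope by design — hence
the always-on advisory. Efficacy itself is not modelled; the package computes
volumes, not biology.
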