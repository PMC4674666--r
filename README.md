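# eggarrange

Quantify the arrangement of a clutch of eggs in a nest cup from annotated
overhead photographs, and simulate and analyze a three-treatment
experimental brood-parasitism study.

Some host birds might detect brood parasitism indirectly, from the
disruption a visiting parasite causes to the arrangement of their clutch.
Testing that hypothesis requires measuring "how much did the clutch
arrangement change" between a before and an after photograph, and relating
the size of that change to the host's behavioral response (deserting the
clutch, ejecting the foreign egg, and how fast). This package provides
that measurement and analysis pipeline for researchers in avian behavioral
ecology, plus a synthetic clutch generator so the whole pipeline can be
validated without field photographs.

## What it computes

**Per-egg arrangement metrics** (from nest center $c$, blunt pole $b$,
sharp pole $s$, in image pixels):

| metric | definition | type |
|---|---|---|
| blunt pole distance | $\lVert b - c\rVert$ | linear |
| blunt pole angle | angle of $c\to b$ from the $+x$ axis | directional, period 360° |
| blunt pole orientation | angle of the long axis from the $+x$ axis | axial, period 180° |
| adjacent angles | axial difference between neighbouring long axes, eggs ordered clockwise, ring closed | axial, period 180° |

**Nest-level change scores**: for each metric, the per-egg two-point SD
over its before/after values, averaged over host eggs — $|\Delta|/\sqrt2$
for the distance, the circular SD $\sqrt{-2\ln\cos(\Delta/2)}$ for the
directional angle, and its doubled-angle analogue for axial metrics, so
wrap-around is handled correctly.

**Mask dissimilarity**: before/after binary clutch silhouettes are
registered (centroid translation + isotropic area-matching scale), then a
pixel of either mask is *matched* if the other mask's Euclidean distance
transform there is at most `tolerance_px`; the score is the proportion of
unmatched pixels in the union of the foregrounds — 0 for identical
clutches, up to 1 for completely displaced ones.

**Statistics**: per-group desertion/ejection rates; Fisher's exact test
(full enumeration and Monte Carlo p with 100,000 replicates); binomial
GLM (logit) for ejection on the parasitized groups; negative-binomial GLM
(log) for latency; likelihood-ratio term tests, Bonferroni family-wise
Wald CIs, VIF, Nagelkerke pseudo-R²; and backward elimination that always
retains the treatment term, reporting both full and final models.

## Worked example

```r
library(eggarrange)

g <- generator_config()                    # 19/30/30 design, 4-5 egg clutches
before <- generate_clutch(g, clutch_size = 5, nest_id = "n1", seed = 42)
after  <- apply_treatment(before, "rearranged", g, seed = 43)

arrangement_change(before, after)
#>   nest_id sd_blunt_pole_distance sd_blunt_pole_angle sd_blunt_pole_orientation
#> 1      n1               7.906122            112.6185                  10.89343
#>   sd_adjacent_angle
#> 1          14.15558

mask_dissimilarity(render_mask(before, g), render_mask(after, g))
#> dissimilarity = 0.5798 (tolerance 2 px, 8312/14416 unmatched)
```

The shuffle moved a typical blunt pole by about `7.9 * sqrt(2) ≈ 11` px
(≈ 5.6 mm at 2 px/mm), rotated blunt-pole bearings and long axes
substantially (the angular SDs are in degrees), and left only ~42% of the
registered silhouettes matching within the 2 px tolerance — a "rearranged"
level of disruption, compared with ≈ 0.02 typical for controls.

Recomputing the study's published outcome rates from its outcome counts:

```r
rep <- reproduce_printed_results(seed = 1)
rep$rates
#>    treatment  n n_desert desertion_pct n_outcome n_eject ejection_pct
#> 1    control 19        2      10.52632        17       0           NA
#> 2   constant 30        5      16.66667        24      19     79.16667
#> 3 rearranged 30        3      10.00000        27      24     88.88889
rep$fisher
#> Fisher's exact test (2x2): p = 1 (Monte Carlo p = 1, 100000 replicates)
#> conditional MLE odds ratio = 0.767, CI [0.0726, 4.4]
```

Desertion is unrelated to treatment (p = 1.00: the observed table is the
conditional mode), so deserted nests are excluded and ejection is compared
between the constant (79.2%) and rearranged (88.9%) groups.

A full simulated experiment — generation, treatment, measurement, outcome
simulation, and the complete statistical stage — is one call:

```r
report <- run_experiment(run_config(seed = 1, outdir = "run1"))
print(report)   # group means, rates, Fisher test, final models
```

## Vignette

`vignettes/egg-arrangement.Rmd` documents the model and its assumptions:
coordinate and angle conventions, the circular/axial statistics, the
registration and tolerance choices in the dissimilarity score, what the
synthetic generator does and does not emulate, the GLM and
backward-elimination conventions, and the simulation sizes used for
validation.
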