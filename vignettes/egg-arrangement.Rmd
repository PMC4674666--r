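---
title: "Quantifying egg arrangement and simulating an experimental parasitism study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying egg arrangement and simulating an experimental parasitism study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Some birds may use the spatial arrangement of their clutch as an indirect
cue that a brood parasite has visited the nest: a parasite landing on the
nest, removing an egg, or depositing her own egg inevitably shuffles the
host's eggs. Testing this "egg arrangement hypothesis" experimentally
requires (i) a way to *quantify* how much a clutch's arrangement changed
between two overhead photographs, and (ii) a statistical comparison of
host responses (desertion, ejection of the foreign egg, latency to
ejection) across treatments that disrupt the arrangement to different
degrees: a control (hand held over the cup, nothing touched), a
*constant* treatment (one non-mimetic model egg added at the cup
perimeter, host eggs otherwise left in place), and a *rearranged*
treatment (host eggs deliberately shuffled before the model egg is
added).

`eggarrange` implements both halves as a reusable pipeline, together with
a synthetic clutch generator so that every stage can be exercised and
validated without access to any field photographs.

```{r, eval = FALSE}
library(eggarrange)
report <- run_experiment(run_config(seed = 1))
print(report)
```

## Arrangement metrics

Each egg in an annotated photograph contributes four measurements,
computed from the nest-cup center $c$, the blunt-pole position $b$, and
the sharp-pole position $s$ (all in image pixels):

* **blunt pole distance** $\lVert b - c \rVert$;
* **blunt pole angle**: the angle between the positive $x$ axis and the
  vector $c \to b$, a *directional* quantity with period $360^\circ$;
* **blunt pole orientation**: the angle between the positive $x$ axis
  and the egg's long axis (the undirected line through $b$ and $s$), an
  *axial* quantity with period $180^\circ$ — swapping the poles cannot
  change it;
* **adjacent angles**: with the eggs ordered clockwise (as displayed in
  the photograph) by blunt-pole polar angle, the axial difference
  $(\theta_N - \theta_{N+1}) \bmod 180^\circ$ between the long-axis
  orientations of each cyclic pair of neighbours. The ring closes
  (egg $N$ pairs with egg 1), so $N$ eggs give $N$ adjacent angles whose
  signed cyclic differences telescope to $0 \bmod 180^\circ$.

**Coordinate convention.** Annotations are in image coordinates (origin
top-left, $y$ down). All angles are computed after flipping to a
mathematical $y$-up frame, so they increase counter-clockwise in that
frame — equivalently, clockwise as the photograph is displayed, which is
also how ImageJ's angle tool reads. The blunt-pole angle uses the
direction *center to blunt pole*. Both choices are conventions that had
to be fixed; every metric is either invariant to them (distance,
adjacent angles) or used only through before/after *differences*, which
cancel the reference.

### Change scores

For each nest the before and after photographs give each metric two
values per egg; the nest-level change score for a metric is the mean
over host eggs of the per-egg two-point standard deviation:

* linear metric (distance): $\mathrm{SD}(x_1, x_2) = |x_1 - x_2| /
  \sqrt{2}$;
* directional angle: the circular standard deviation (Mardia),
  $\sqrt{-2 \ln \bar R}$ in degrees, which for a two-point sample
  reduces to $\sqrt{-2\ln\cos(\Delta/2)}$ where $\Delta$ is the
  circular difference — computed in this closed form so identical
  angles give exactly zero;
* axial angle: the same on doubled angles, halved.

The per-egg-then-average order (rather than pooling all eggs into one
SD) was an open design choice; per-egg pairing keeps the score
interpretable as "how much did a typical egg move" and is invariant to
clutch size. Host eggs are paired across phases by `egg_id` when the
identifiers match, otherwise by exhaustive minimum-total-distance
centroid assignment (clutches have at most five host eggs, so all
permutations are enumerable). The added model egg has no "before" state
and is excluded from all paired metrics; it *is* included in the
rendered silhouette, so the mask dissimilarity sees it. Adjacent pairs
are fixed by the before observation's clockwise ordering and the same
egg pairs are re-measured after manipulation, keeping pair identity
stable when the shuffle reorders the ring.

A numerical edge case: an exactly antipodal two-point sample
($\Delta = 180^\circ$ directional, $90^\circ$ axial) has $\bar R = 0$
and infinite circular SD. This has probability zero under the
continuous generator and did not occur in any validation run; real
annotations that trigger it indicate a digitisation error.

## Mask dissimilarity

The whole-clutch comparison is a proportion-of-mismatch score between
the binary silhouettes of the before and after clutch:

1. **Registration**: the moving mask is translated so the two
   foreground centroids coincide and isotropically rescaled so the
   foreground areas match (nearest-neighbour, re-binarized). No
   rotation is searched — the photographs share a consistent overhead
   framing, and rotating would cancel exactly the arrangement change
   the score is meant to capture. If real photographs with inconsistent
   framing are ever analysed, this assumption must be revisited.
2. **Tolerance matching**: a pixel of either mask counts as matched if
   the other mask's Euclidean distance transform at that pixel is at
   most `tolerance_px`.
3. **Score**: unmatched pixels of both masks divided by the pixels in
   the union of the two registered foregrounds, so the score is a
   proportion in $[0, 1]$, 0 for identical masks, and independent of
   the frame size.

Because nearest-neighbour resampling is not symmetric in its arguments,
the score is computed in both registration directions and averaged,
making it exactly symmetric. It is non-increasing in the tolerance and
reaches 0 as the tolerance grows without bound. The default
`tolerance_px = 2` absorbs resampling error at the default rendering
scale of 2 px/mm (i.e. a 1 mm physical tolerance); the tolerance is a
physical length, so analyses that change the image scale should scale
it alongside — at a fixed pixel tolerance the score is only
scale-invariant in the zero-tolerance (pure XOR/union) limit.

## The synthetic generator

The generator emulates the experimental design, not the photographs:

* clutches of 4 or 5 host eggs (equal probability) in a circular cup of
  radius 50 mm, a typical blackbird cup — host eggs 29 × 21 mm, values
  typical for the species; the model egg is 22.40 × 16.89 mm, the
  published dimensions of the foreign egg model;
* eggs are placed without overlap (verified against a rasterized
  oracle), long axes roughly radial with blunt poles biased outward,
  as thrush clutches sit in a cup;
* group sizes default to 19/30/30 (control/constant/rearranged), the
  field sample sizes;
* **control**: every host egg center is jittered by isotropic Gaussian
  noise (`jitter_sd_mm`, default 1 mm) and its orientation by 5°,
  representing photographic/handling noise — no magnitude is published
  for it, so this default is a choice and is reported with all results;
* **constant**: the model egg is added at the cup perimeter; inserting
  it contacts and nudges neighbouring eggs, modeled as the control
  jitter inflated by `constant_disturbance_multiplier` (default 2).
  Some extra disturbance of the host eggs is required for the constant
  group to disrupt the *host-egg* metrics more than the control does —
  the observed pattern this generator is built to emulate — because the
  model egg itself is excluded from the paired metrics;
* **rearranged**: host positions and orientations are redrawn
  (`shuffle_intensity = 1`; intermediate values interpolate), a
  magnitude-level model of the 10-second figure-eight hand shuffle —
  only the size of the disruption matters downstream, not the path;
* **outcomes**: desertion is Bernoulli with a treatment-independent
  probability (default 10/79, the pooled field rate); non-deserted
  parasitized nests eject with log-odds $1.34 + 0.74 \cdot
  [\text{rearranged}]$, the published final-model estimates (equal to
  the logits of the observed 79.2% and 88.9% ejection rates); ejection
  latency is negative-binomial ($\theta = 2$) with log-mean $0.37 -
  1.21 \cdot [\text{clutch of 5}]$, again the published estimates.
  Latency draws beyond the 6-day monitoring window are resampled rather
  than censored — the fitted model treats latency as a plain count, so
  resampling keeps the simulated support honest at the cost of a small
  truncation bias in recovered coefficients (≈5% at the default
  parameters).

What the generator does **not** emulate: real feather/nest-material
segmentation noise, lighting, perspective, partially occluded eggs,
non-random disruption by a real parasite, or multi-day arrangement
drift. Passing tests therefore validate the *measurement and inference
machinery*, not the biological claim on real photographs.

## Statistical stage

Mirroring the original analysis:

* deserted nests are excluded from the response analyses (desertion was
  unrelated to treatment); desertion itself is tested with Fisher's
  exact test on the control vs parasitized 2 × 2 table, with both the
  full-enumeration p-value and a Monte Carlo variant
  ($(1 + \#\{\text{simulated tables at most as probable}\}) /
  (n_{\text{reps}} + 1)$, 100,000 replicates by default);
* ejection (binary) is a binomial GLM with logit link on the two
  parasitized groups only — a control nest has no foreign egg to eject,
  so treatment is a single-df constant vs rearranged contrast;
* latency (days, 0 = same-day ejection) is a negative-binomial GLM with
  log link. The original description says "mixed models" but lists no
  random term and has one observation per nest, so no grouping factor
  is identifiable; a fixed-effects NB GLM is the fitted structure. When
  the dispersion estimate diverges (Poisson-like or degenerate data)
  the model falls back to Poisson and flags it;
* covariates: nest age, laying date, clutch size (categorical 4 vs 5);
* **backward elimination** removes the least significant term with
  $p > \alpha$ (default 0.05) and refits, repeatedly; the treatment
  term is protected and always retained. Both the full and the final
  model are reported;
* per-term significance is the single-term-deletion likelihood-ratio
  $\chi^2$; confidence intervals are Wald, family-wise over the model's
  coefficients by Bonferroni (the original does not name its
  adjustment; Bonferroni is the conservative default); collinearity is
  reported as VIF ($1/(1-R^2_j)$); the pseudo-$R^2$ is Nagelkerke,
  labeled as such in the output. Perfect separation in the binomial
  model is flagged and a data-augmentation penalized refit (pseudo-
  observations at the predictor means, acting as a weak prior) is
  attached for inspection.

## Validation by simulation

Because the raw field data are not deposited, the published model
*coefficients* are not reproducible; the published *percentages* and
the Fisher test are (they follow from printed counts), and the model
machinery is validated by parameter recovery instead. The test suite
checks, at sizes chosen to keep Monte Carlo error well below the
assertion bands:

* Wald 95% CI coverage of the treatment log-odds (0.74) and the
  clutch-size latency effect (−1.21) over 1,000 simulated replicates of
  400 parasitized nests: within 95% ± 2%;
* type-I error of the treatment term under a zero treatment effect:
  5% ± 2%;
* backward elimination retains treatment in 100% of replicates and
  drops each null covariate at a rate consistent with $1 - \alpha$;
* with 200 simulated nests per group under the default configuration,
  the group means of the mask dissimilarity *and* of all four
  arrangement-SD metrics are strictly ordered
  control < constant < rearranged — the qualitative validation result
  that the treatments successfully manipulated every arrangement
  metric;
* all four geometry metrics agree with an independent complex-
  arithmetic reimplementation to $10^{-9}$ on random clutches, and the
  two-point circular SDs with a unit-vector oracle.

One published quantity is deliberately not asserted: the Fisher odds
ratio printed as 0.67 is not recoverable from the implied 2 × 2 table
(the conditional MLE is ≈ 0.77); the table's p-value of 1.00 is
reproduced exactly.

## Reproducibility

Every stochastic stage takes an explicit seed; `run_experiment()`
derives per-stage seeds from one master seed with a documented linear
scheme (`stage_seed()`), so any stage can be rerun in isolation and a
written `config.json` snapshot reproduces an archived run byte for
byte. All tabular outputs are plain CSV with fixed column order.
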