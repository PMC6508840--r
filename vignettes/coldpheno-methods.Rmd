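---
title: "Methods: quantifying maize seedling cold-stress recovery from side-view images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying maize seedling cold-stress recovery from side-view images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldpheno)
```

## The measurement problem

A maize seedling moved into a cold incubator (6 °C day / 2 °C night) for a
couple of days stops growing, may develop brown necrotic leaf tissue, and —
once returned to warm conditions — resumes growth at a genotype-dependent
rate. `coldpheno` turns daily side-view RGB images of potted seedlings
(three pots per image, photographed against a blue backdrop above a dark
pot rack) into quantitative descriptions of that recovery:

1. every pixel is classified as background, healthy or necrotic tissue by
   a naive Bayes colour model;
2. the classified masks are cleaned, the rack's top edge is detected, and
   everything at or below it is excluded so soil and rack pixels never
   reach trait extraction;
3. sixteen morphological traits plus percent necrosis are measured per
   plant per day;
4. per-plant growth rates over defined intervals, their log2 fold changes
   between cold and control treatments, and a per-genotype necrosis ANOVA
   summarize recovery;
5. the genotype-by-feature matrix of fold changes (the "phingerprint") is
   hierarchically clustered to group genotypes by response type.

Every stage is exercised end to end on a bundled synthetic image and
trait-trajectory generator with exact ground truth, so the package is
fully testable without downloading any imagery.

## Pixel classification

For class $c$ and channel $x \in \{R, G, B\}$ the classifier stores a
Gaussian-kernel density estimated from the training pixels, evaluated on
the integer grid $0..255$ and renormalized:

$$\hat f_{c,x}(b) = \frac{1}{n_c} \sum_i \phi\!\left(\frac{b - x_i}{h_{c,x}}\right), \qquad b = 0, \dots, 255.$$

Pixel posteriors assume channel independence,
$P(c \mid r, g, b) \propto \pi_c\, \hat f_{c,R}(r)\, \hat f_{c,G}(g)\, \hat f_{c,B}(b)$,
and the label is the maximum-posterior class.

Numerical and design choices:

* **Bandwidth** $h$ defaults to Silverman's rule per class and channel,
  floored at 0.5 bins so constant-valued channels still yield a proper
  density; it can be fixed globally.
* **Density floor** of $10^{-9}$ per bin (before renormalization) keeps
  colours absent from training from zeroing the posterior everywhere;
  pixels at the floor for *every* class are assigned background and
  flagged.
* **Ties** are broken by the fixed order background > healthy > necrotic,
  so classification is deterministic.
* **Colour space** is RGB by default — the training table is RGB and the
  generator renders RGB, which keeps the chain self-consistent — with an
  HSV option (`colorspace = "hsv"`) for workflows that train in HSV.
* **Background is a trained class**, not a blue threshold: the backdrop
  dominates the scene and a generative treatment keeps the model
  symmetric. Rack pixels are pooled into the background class when
  sampling training data.
* Colour overlap between soil, stem and necrotic tissue is *not* resolved
  by the classifier; the rack-line exclusion below is the remedy, and the
  generator's misclassified-stem baseline emulates the residual artifact.

## Mask cleanup and rack exclusion

`dilate_fill()` applies square-kernel dilation (radius 1 by default, one
iteration) followed by hole filling. The dilated-and-filled mask defines
the cleaned *object region*; per-class pixel counts (area, healthy,
necrotic) and shape traits are measured on the classified pixels inside
that region, never on the dilated mask itself — a radius-1 dilation adds
roughly one perimeter's worth of pixels, which would bias the area of a
desk-scale seedling by tens of percent.

`detect_rack_line()` scores each row in the bottom half of the grayscale
image by the mean absolute vertical intensity step and returns the
arg-max row — the backdrop-to-rack transition. The search region keeps
leaf edges higher in the frame from competing. A winning score below 5
intensity units raises a "rack not found" error rather than returning a
spurious row. Pixels at or below the boundary are excluded
(half-open convention: the plant region is strictly above the boundary
row).

Plants are split by fixed equal-width pot strips, not connected
components: touching leaves of neighbouring plants would merge
components, while pots sit at fixed rack positions. A leaf crossing a
strip boundary is split between pots — a documented limitation; pixel
counts are conserved.

## Traits

Sixteen morphological traits are emitted per plant: height, width, area,
perimeter; convex-hull area, vertex count, longest axis and solidity;
moments-ellipse centre (x, y), major and minor axis, angle and
eccentricity; and centre-of-mass x and y. Conventions, where more than
one definition is defensible:

* Extents are inclusive (+1), so a single pixel has height = width = 1.
* Area counts every plant pixel of either tissue class;
  percent necrosis is $100 \cdot \text{necrotic} / \text{area}$.
* The perimeter is the traced boundary length of the largest 8-connected
  component, with diagonal steps counting $\sqrt 2$ (not a boundary-pixel
  count).
* The hull is taken over pixel centres with collinear vertices removed;
  `hull_area` is the number of pixel centres on or inside the hull
  polygon (computed from the shoelace area via Pick's theorem), so a
  filled convex shape has solidity exactly 1 and solidity never exceeds
  1. Degenerate (collinear) sets use the pixel count, keeping solidity
  defined.
* Ellipse axes are full lengths $4\sqrt{\lambda}$ of the coordinate
  covariance eigenvalues, so a rasterized disk's major axis equals its
  diameter; the angle is the major eigenvector's orientation from the +x
  axis in $[0, 180)$; eccentricity is $\sqrt{1 - (b/a)^2}$. Collinear
  sets report a zero minor axis and missing eccentricity.
* Empty pots yield an all-missing trait record, never a dropped row.

Image coordinates are origin top-left, x rightward, y downward; the rack
occupies high-y rows. All modules share this convention.

## Growth statistics

Cold-stressed plants sit still for the stress duration, so comparing
treatments at equal age compares different developmental stages. The
time-shift alignment assigns cold observations
`aligned_das = das - shift_days` (default 2, the stress length) and drops
records that fall outside the control day range. On the shifted axis the
default intervals are **early recovery** (aligned DAS 9–11, i.e. cold
plants' DAS 11–13) and **late recovery** (aligned DAS 11–14); both are
configurable, and interval names travel through all outputs.

Per plant, trait and interval, the growth rate is the OLS slope of value
on aligned day (at least two distinct days required; plants failing this
are excluded from that interval with a message). Slopes are averaged per
genotype, treatment, trait and interval with a standard error; plants are
pooled across biological replicates, with the replicate retained as a
column, since slope averaging is associative and the replicate effect is
not modelled (a deliberate simplification — no mixed-effects modelling).

The treatment contrast is
$\log_2\!\big(\max(\text{cold}, \varepsilon) / \max(\text{control}, \varepsilon)\big)$
with $\varepsilon = 0.01$ trait units/day. Growth arrest makes zero or
negative slopes a real possibility; clipping with an explicit
`clipped` flag keeps every genotype in the matrix while marking saturated
values, rather than dropping them or producing infinities.

Percent necrosis is compared at a single day (default 13 DAS — two days
after the default stress ends, where the trajectory peaks before new
healthy growth dilutes a fixed necrotic mass). Per genotype, a classic
equal-variance one-way ANOVA across treatments with a post-hoc Tukey HSD
adjusted p-value; a genotype is called significant only for an increase
(adjusted p ≤ α **and** cold mean above control mean). Welch's ANOVA
would be more robust to variance heterogeneity; the classic form matches
the named procedure and is noted as a limitation. With two treatments the
Tukey-adjusted p equals the plain ANOVA p, which the tests assert.

## Phingerprint clustering

The phingerprint matrix has one row per trait-by-interval log2 fold
change (trait alphabetical within interval order) plus, by default, one
necrosis row — the cold-minus-control mean percent necrosis at the test
day. A difference rather than a log ratio, because control necrosis can
be arbitrarily close to zero; whether necrosis enters as one feature,
several, or none is configuration, since reasonable layouts differ.
Missing genotype-feature combinations are an error, never imputed. Rows
are z-normalized by default, which makes the cluster choice invariant to
per-feature affine rescaling.

Genotype columns are clustered agglomeratively with Euclidean distance
and complete linkage (the defaults of the common heatmap tooling this
workflow mirrors); both are configurable. The cluster count is chosen by
maximizing the mean silhouette width over a scan (default k = 2–6, ties
to the smallest k) — an explicit, testable criterion in place of choosing
a cut by eye. Columns are sorted by genotype name before clustering so
distance ties resolve deterministically. If all profiles are identical
the result is a degenerate single cluster with a warning.

## What the synthetic generator emulates — and what it does not

The generator defines the study conditions the package is validated
under: nine daily time points (DAS 8–16), a 2-day cold stress starting at
DAS 9, three biological replicates of two three-plant plots per genotype
and treatment (18 plants per group), and a 40-genotype panel drawn from
three response archetypes — tolerant (full recovery, no necrosis
response), sensitive (recovery multiplier 0.6, strong necrosis), and
intermediate (multiplier 0.8 with height recovery specifically reduced
and width recovery spared, moderate necrosis). Which traits a response
touches differs between archetypes, mirroring the observation that
response patterns, not just magnitudes, distinguish genotypes. Seven of
forty lines are sensitive, the designed fraction of strong necrosis
responders.

The growth model is piecewise linear: every trait grows at a
genotype-scaled base rate, arrests exactly during the cold window, and
resumes at the archetype multiplier. Necrotic pixels are a fixed
genotype-specific fraction of plant area (the misclassified lower-stem
artifact, present in *all* treatments, rate drawn uniformly on [0, 0.1] —
the real distribution is unknown, so this is an explicit modelling
choice) plus, after the stress, a mass that accumulates linearly over a
2-day lag and then stays constant. Under the defaults this puts the
percent-necrosis peak at 13 DAS, with the subsequent decline produced by
healthy regrowth.

Noise has three explicit dials: a persistent per-plant size scale
(sd 0.05), per-observation Gaussian noise with sd 10% of the true value,
and an optional independent relative noise on necrotic counts
(`necrosis_noise_sd`, default 0). Under the default of 0, a genotype's
control percent necrosis is exactly its stem baseline — plant-level size
noise cancels in the ratio — so genotypes with no treatment effect are
structurally never flagged by the day-13 ANOVA, and calibration studies
that need null dispersion switch the dial on explicitly.

Rendered plot images place one plant per fixed pot strip (stem rectangle
plus a distance-filled elliptical canopy whose pixel count equals the
requested area exactly), a dark rack band with a recorded top row, and
per-class Gaussian colour noise around configurable means. Rendering is
bitwise-deterministic given a seed. Table-only mode skips rendering and
emits the trait table directly — the statistical stages need thousands of
plants, which imaging at desk scale would make needlessly slow; image
mode is exercised at small scale (a 36-image fixture).

Deliberately not modelled: photorealism, leaf occlusion between
neighbouring plants (the assay stops at DAS 16 for exactly that reason),
chlorosis as a separate class, QR-code or colour-standard regions, and
any real-image idiosyncrasies (lighting drift, pot misplacement, camera
tilt). Passing tests therefore demonstrate the pipeline's correctness
and statistical calibration under the generative model, not performance
on real photographs.

## Problem sizes used in validation

The test suite validates the statistical stages at two scales, chosen
once as part of the study design: the paper-like scale (18 plants per
genotype and treatment) for the necrosis ANOVA — where the designed
7-of-40 strong responders are recovered exactly — and a larger
table-only run (81 plants per group, ~6,500 plants) for phingerprint
clustering, where per-feature fold-change noise is small enough that
silhouette selection chooses k = 3 and the adjusted Rand index against
the true archetypes reaches 0.9 or better. Slope estimation noise scales
as $1/\sqrt{n}$, so cluster recovery at the smaller scale is not
expected and not asserted.

## Known limitations

* Strip splitting misassigns pixels of leaves that cross pot boundaries.
* The rack-line rule is a reconstruction validated against the generator
  only; real racks with texture or reflections may need a different
  operator.
* The classic ANOVA assumes equal variances; the deterministic-baseline
  necrosis model makes control groups nearly noise-free, which is the
  most favourable case for it.
* No multiple-testing correction is applied across genotypes in the
  necrosis scan (only Tukey's within-genotype adjustment), matching the
  analysis the package reproduces.
* The two traits beyond the fourteen named ones are taken to be the
  centre-of-mass coordinates; other choices are defensible.
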