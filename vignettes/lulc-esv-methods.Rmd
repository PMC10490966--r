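---
title: "Methods: LULC change detection and ecosystem service valuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LULC change detection and ecosystem service valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lulcesv)
```

# Scope

`lulcesv` chains five stages: simulation of multi-epoch land-cover scenes,
Gaussian maximum-likelihood classification (plus NDVI density classes),
confusion-matrix accuracy assessment, post-classification change detection,
and benefit-value-transfer valuation with a coefficient-of-sensitivity
analysis. This vignette records the models, the assumptions, the tunable
parameters, and the numerical and design choices behind each stage.

# The synthetic-scene generator

`scene_spec()` + `generate_class_series()` simulate K categorical cover
classes on a pixel grid evolving across epochs under a first-order Markov
model: epoch 1 is drawn i.i.d. from the initial class proportions, and each
later epoch re-draws every pixel's class from the transition-probability row
of its current class, independently per pixel. `render_spectra()` then draws
each pixel's B-band reflectance vector from its class's multivariate
Gaussian, and `sample_ground_truth()` samples labelled points without
replacement per class — the synthetic analogue of GPS-referenced reference
data.

What the generator deliberately emulates:

* a six-class highland legend (forestland, cultivated, grassland, built-up,
  barren, water) on a 30 m grid, four epochs labelled 1984/1991/2001/2021;
* initial proportions (10.8% forest, 33% cultivated, 26.5% grassland, 12%
  built-up, 10.8% barren, 6.9% water) and a per-step transition matrix with
  conversion pressure toward cultivated and built-up land — the
  agricultural-expansion regime in which natural classes shrink
  monotonically while water declines fastest;
* per-class Gaussian band models whose means are NDVI-consistent: the NDVI
  of each class mean falls in the density interval conventionally associated
  with that cover (water −0.50; built-up 0.043; barren 0.063; cultivated
  0.20; grassland 0.28; forest 0.50), so maximum-likelihood classification
  and NDVI binning agree on what the fixture "is";
* a nodata mask (default 2%) drawn once at epoch 1 and held fixed, so
  cross-tabulations between epochs are defined on a constant support;
* 50 reference points per class by default.

What it does **not** emulate, and hence what passing tests do *not*
demonstrate about real imagery: spatial autocorrelation (pixels evolve
independently; real landscapes change in patches), mixed pixels and class
gradients, atmospheric and illumination effects, sensor striping and cloud
artefacts, and seasonal phenology. Results on the generator certify the
*bookkeeping and estimation machinery*, not classifier performance on
Landsat scenes.

Separability is a free parameter. The default band standard deviation
(0.005 per band, diagonal covariance) puts the closest class pair
(grassland vs cultivated) about 7.7 Mahalanobis units apart, so the default
fixture is a well-separated scene on which classification should be nearly
perfect; tests that need a harder problem raise the covariance explicitly.

Seeding: one master seed lives in the spec; every stochastic operation
derives a sub-stream seed deterministically from (master, tag), where the
tag names the epoch or operation. Adding epochs or stages therefore never
perturbs earlier draws, and identical specs give bit-identical scenes,
spectra and ground truth.

# Classification

`fit_signatures()` estimates each class's mean and covariance (denominator
n − 1) from training pixels. Small training sets can give numerically
singular covariances; when the smallest eigenvalue is below 1e-10 times the
largest, a ridge ε·I is added with ε = 1e-6 × mean diagonal, floored at
1e-6 when the diagonal itself is zero (the degenerate case of identical
training pixels). The threshold and magnitude are deliberately tiny: the
ridge exists to make the discriminant defined, not to shrink estimates.

`classify_max_likelihood()` assigns each non-nodata pixel the class with
the highest Gaussian log-density under equal priors — plain maximum
likelihood rather than maximum a posteriori, because no defensible prior
class frequencies exist before the map is made. Ties are broken toward the
lowest class code for determinism. The implementation evaluates the
quadratic forms through a Cholesky factor per class; the test suite checks
it pixel-for-pixel against an independent brute-force `solve()`/`det()`
evaluation, and against the closed-form reduction to nearest-mean
Mahalanobis classification when all classes share one covariance.

NDVI is (NIR − R)/(NIR + R); pixels with NIR + R = 0 become undefined
(nodata) rather than 0, since 0 would silently read as "sparse vegetation".
Values are clamped to [−1, 1] only when round-off exceeds the bounds by
less than 1e-12. The five density classes use half-open, lower-inclusive
intervals [−1, −0.03), [−0.03, 0.15), [0.15, 0.25), [0.25, 0.35),
[0.35, 1]: published threshold lists for these classes share endpoints, and
the half-open convention (boundary assigned upward, top bin closed) is the
unique resolution that partitions [−1, 1] without gaps or overlaps. The
fourth class is named by its density ("moderate vegetation") with
"grassland" noted as its conventional cover alias in the legend
description.

# Accuracy assessment

`build_confusion()` fixes reference classes in rows and mapped classes in
columns; producer's accuracy uses row sums, user's accuracy column sums.
Classes absent from both sides are dropped rather than zero-padded so the
kappa denominator M² − Σ n_i n_j stays meaningful. Kappa is reported with
the conventional agreement bands (> 0.80 strong, 0.40–0.80 moderate,
< 0.40 poor) and is explicitly undefined (NA) when only one class is
nonempty. Percentages are formatted with half-away-from-zero rounding.

# Change detection

Areas convert pixel counts at pixel_size²/10⁴ ha per pixel. The annualized
rate divides the relative area change by the period length t in years —
note this is the simple-interest convention (not a compound/exponential
rate), so reversing the endpoints flips the sign but rescales the magnitude
by the new denominator. `cross_tabulate()` restricts to pixels non-nodata
in *both* epochs; its row totals therefore reproduce the epoch-A area table
and its column totals the epoch-B table exactly (a conservation identity
the tests assert), and net changes sum to zero over classes by
construction. Np is reported as NA when a class has zero persistence.

# Valuation

Benefit value transfer assigns each class a vector of 17 per-function value
coefficients VC_kf (US$ ha⁻¹ yr⁻¹); the packaged default is the modified
conservative coefficient set for tropical Afromontane landscapes (class
totals: forest 986.69, cultivated 225.56, grassland 293.25, water 8103.5,
built-up and barren 0). Built-up and barren rows are identically zero —
those covers are attributed no ecosystem service value, so they contribute
nothing and their sensitivity is zero by definition. `load_coefficients()`
validates the per-class sums against the table's declared totals to 0.01
and treats blank cells as zeros. The BVT assumption worth keeping in mind:
coefficients are spatially uniform per class, so ESV maps linearly through
areas and carries no within-class heterogeneity.

Per-class, per-function and total values are the three marginal sums of
A_k · VC_kf; their agreement is asserted on random tables as a property
test. Values are held in US$ at double precision internally and reported in
millions at one decimal, rounded half away from zero.

Percent change has two modes. `"raw"` uses the values as computed;
`"paper"` (the default for table comparison) first rounds both operands to
0.1 million US$, because published change percentages are computed from the
tabulated one-decimal values — e.g. a forest decline of 10.563→4.939
million US$ is −53.2% raw but −53.8% from the rounded 10.6→4.9. Changes are
always reported as loss/gain relative to the *start* value; a "−67.3%"
total decline means 32.7% of the initial value remains.

Classes whose area is unknown but whose value is published can enter
through `extra_esv` as a fixed per-class US$ amount; per-function marginals
apportion such a class over functions in proportion to its coefficient row.
This is how cultivated land (no endpoint areas published) joins the
endpoint-year totals in the worked example.

## Coefficient of sensitivity

CS is the elasticity of the total ESV with respect to one class's
coefficient vector, estimated by scaling that class's whole row by
(1 + δ) (default δ = ±0.5) and recomputing the total. Because the
perturbation is proportional to the entire row, CS reduces *exactly* to the
class's share of the total value, ESV_k / ESV_total — independent of δ's
magnitude and sign. The implementation nevertheless performs the actual
recomputation, and the identity (checked to 1e-12 for δ ∈ {±0.1, ±0.5,
±0.9}) serves as its closed-form oracle. CS > 1 would mean the estimate is
elastic (fragile) in that coefficient; every class in the packaged
configuration is inelastic.

# Pipeline, formats, reproducibility

`run_pipeline()` composes all stages and writes every artifact plus a
manifest JSON with MD5 checksums; identical seeds give byte-identical
artifacts. `run_valuation_only()` exposes the valuation sub-pipeline for
area tables supplied directly (CSV), producing numbers identical to the
full pipeline on the same areas. Rasters are exchanged as ESRI ASCII grids
(plain-text, carrying cellsize and NODATA in the header; class maps use
NODATA 0, NDVI −9999), multi-band scenes as one grid per band with a YAML
sidecar for band roles; points, signatures, areas, transitions and reports
are CSV/JSON. A thin command-line front end (`inst/cli/lulcesv.R`) maps
subcommands (simulate, classify, ndvi, accuracy, change, esv, sensitivity,
run-all) onto the same functions.

# Problem sizes and limitations

The test suite exercises statistical contracts at sizes chosen to make
law-of-large-numbers tolerances sharp but runs fast: Markov recovery and
moment checks on 200×200 grids (±0.02 on transition cells), classifier
oracle equivalence at 100×100 with 6 classes, and a full 4-epoch 200×200
end-to-end run in which recovered areas and the ESV trajectory must land
within 1% of the analytic values from the true maps.

Known limitations: no spatial autocorrelation in the generator (see above);
no per-pixel ESV surfaces (valuation is per-class, so a map would be
cartography over the same numbers); no variance or confidence intervals for
kappa and no area-weighted accuracy adjustment; no alternative classifiers;
the simple-interest change-rate convention; and the BVT uniform-coefficient
assumption inherited from the method itself.
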