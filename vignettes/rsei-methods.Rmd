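---
title: "Methods: composing a remote sensing ecological index for a coastal saline-alkali reserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composing a remote sensing ecological index for a coastal saline-alkali reserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rseikit)
```

## The problem

Small coastal reserves -- here, a tamarisk (*Tamarix chinensis*) forest on
saline-alkali land by the Laizhou Bay -- need eco-environment assessments
that are spatially continuous, repeatable across dates, and obtainable from
imagery alone. The Remote Sensing Ecological Index (RSEI) answers this by
compressing several indicator rasters into one [0, 1] score per pixel with
a principal component analysis, so no analyst-chosen weights enter the
composite. This package implements a six-indicator variant -- aerosol
optical depth (AOD), soil salinity, greenness, wetness, heat and dryness --
together with the retrievals that produce each indicator from multiband
reflectance, and a synthetic-scene generator that supplies ground truth for
every stage.

## Indicators

**Greenness** is NDVI, `(NIR - Red) / (NIR + Red)`.

**Wetness** is the third tasseled cap component,

$$W = 0.1509\,\rho_2 + 0.1973\,\rho_3 + 0.3279\,\rho_4 + 0.3406\,\rho_8
      - 0.7112\,\rho_{11} - 0.4572\,\rho_{12},$$

applied with the same weights to Sentinel-2A band roles and to the
corresponding Landsat roles.

**Dryness** is the bare soil index, the normalized difference
$[(\rho_{11}+\rho_4) - (\rho_8+\rho_2)] / [(\rho_{11}+\rho_4) +
(\rho_8+\rho_2)]$. The printed source formula lacks the operator in the
numerator; the difference form is adopted because it alone is bounded in
$[-1, 1]$ and spatially inverse to wetness, which is the behaviour the
indicator is defined by.

**Heat** is single-channel land surface temperature: sensor radiance is
atmospherically corrected,
$B(T_s) = [L - L_u - \tau(1-\varepsilon)L_d]/(\tau\varepsilon)$, and
inverted through the band-effective Planck function
$T_s = K_2 / \ln(K_1/B + 1)$. The emissivity, transmissivity, path
radiances and calibration constants are scene metadata (`lst_params()`);
the defaults are a typical thermal-band calibration with a clear
mid-latitude atmosphere. A 30 m thermal product is paired with a 10 m
optical grid by nearest-neighbour resampling (`resample()`), which
preserves the retrieved value set.

**Salinity** comes from a five-band multiple linear regression (or a BP
network, below) on synchronous soil samples. Bands are screened by the
diagnosis index $D_i = 100\,\sigma_i R_i$, where $\sigma_i$ is the
population dispersion of band-$i$ reflectance over the samples and $R_i$
its Pearson correlation with measured soluble salt. $\sigma$ is computed on
reflectance in the units supplied; the reference survey's printed
dispersion table cannot be reconciled with its index table under any single
unit convention, so the statistic is defined self-consistently here and the
printed index values are not asserted anywhere.

**AOD** uses the dense-dark-vegetation method: over dark pixels
(NDVI > 0.3, strict), the top-of-atmosphere reflectance equation
$$\rho^* = \rho_a + \frac{T\rho}{1 - S\rho}$$
is inverted per candidate AOD with lookup-table coefficients
$(\rho_a, T, S)$, and the candidate whose corrected red/blue surface ratio
is closest to $k = 1.60$ wins (ties to the smaller AOD). NDVI for dark
detection is computed from apparent reflectance -- surface reflectance is
not available before the retrieval, so a surface NDVI would be circular.
Non-dark pixels receive an inverse-distance-weighted average (power 2, 12
nearest retrievals) followed by a 3x3 mean filter; the source names the
method but no parameters, so these are package defaults. The candidate
grid defaults to the lookup table's tau axis, which guarantees every
candidate interpolates validly. For sensors with a 2.1 um band the
half/quarter Kaufman relations are provided
(`kaufman_dark_reflectance()`); the printed factors "12" and "14" are read
as 1/2 and 1/4, since reflectance would otherwise exceed one.

## Normalization, PCA and composition

Each indicator is clipped to its 2nd/98th percentile and min-max scaled
("2% confidence interval" normalization; a constant raster maps to 0.5).
Negative-sense indicators (dryness, heat, AOD, salinity) are *not*
inverted first: the reference loadings are signed on un-inverted inputs,
and orientation is handled once, after the projection.

The PCA runs on the covariance matrix of valid-pixel vectors (covariance,
not correlation: the layers already share the [0, 1] scale and their
variances are informative). All valid pixels are used; eigenvalues are
reported descending with contribution rates $100\lambda_i/\sum\lambda$.
RSEI is the PC1 projection, sign-flipped if the greenness loading is
negative so that greener is always better, then min-max rescaled to [0, 1].
Whether the source rescales PC1 or 1-PC1 is not stated; the
greenness-positive rule is this package's declared convention and makes
the choice observable (RSEI correlates positively with greenness by
construction).

**Water masking.** Before normalization the pipeline masks water pixels
(MNDWI $= (\rho_3-\rho_{11})/(\rho_3+\rho_{11}) > 0$). Water is extreme in
wetness, dryness and heat simultaneously; left in, the leading component
of a sparsely vegetated scene degenerates into a water-versus-land axis
and the greenness orientation rule becomes meaningless. Masking water
before an RSEI-style PCA is standard practice for this composite and is a
deliberate design choice here (`mask_water = TRUE`), not a property
inherited from the source description.

Grades partition [0, 1] at 0.2 intervals into Worst, Worse, Medium, Good,
Excellent -- bins left-closed and right-open, top bin closed so 1.0 is
Excellent. Change detection differences two dates and classifies at a
symmetric threshold: Better above +0.1, Worse below -0.1, Unchanged on the
closed interval between.

## The synthetic scene generator

`make_scene()` emulates the study conditions the workflow targets:

* a land-to-sea salinity gradient (0--15 g/kg by default, axis
  configurable, sea at the north edge) whose cross-shore slice means
  increase strictly seaward by construction;
* patchy shrub cover mixed linearly from three endmembers (vegetation,
  bare saline soil, water) such that the fraction of pixels with surface
  NDVI > 0.3 equals the configured `veg_fraction` exactly before noise;
  bare-soil brightness rises with local salt (salt crusts are bright),
  which is what gives the salinity regression its signal;
* a smooth AOD truth field, 0.5--1.4 by default (the range reported for
  the September scene the workflow models), forward-modelled to
  top-of-atmosphere red/blue/NIR through the same lookup-table equation
  the retrieval inverts;
* a temperature truth field anti-correlated with cover (24.55--30.15
  degrees C by default) synthesized to radiance by the Planck forward
  model, so the LST stage is exactly invertible;
* Gaussian band noise (sd 0.005 reflectance) and ~8% near-shore water.

Two constructions deserve emphasis because they define what passing tests
mean. First, on vegetated pixels the aerosol-sensor surface red/blue ratio
is held at exactly $k$; dark-target retrieval *assumes* that ratio, so
enforcing it makes retrieval error isolate the lookup-table inversion step
rather than mixing in surface-model mismatch. Second, the bundled
`synthetic_lut()` is a smooth analytic surrogate for a radiative-transfer
run, not an atmosphere model; scenes are forward-modelled through the same
table the retrieval reads, which is exactly the consistency an operational
lookup table provides. Consequently the generator demonstrates
correctness of the algorithms, not radiometric realism: real scenes add
surface-ratio scatter, sensor PSF, topography and clouds, all declared
out of scope.

## Numerical choices and degenerate inputs

* TOA inversion $\rho = (\rho^*-\rho_a)/(T + S(\rho^*-\rho_a))$ is the
  exact algebraic inverse of the forward equation (round trips to 1e-12);
  a non-positive denominator flags the pixel rather than erroring.
* Lookup-table interpolation is tensor-product multilinear, exact at
  nodes; axes with a single node are treated as constant, which lets a
  printed per-tau excerpt act as a 1-D table (`collapse_lut_tau()`).
* Retrieval ties break toward smaller AOD; candidates whose inversion is
  undefined are skipped, and a pixel with no valid candidate is flagged
  unretrieved.
* The BP network is a single-hidden-layer `nnet` fit on min-max normalized
  inputs/outputs with the hidden size searched stepwise from 2 until the
  training MSE reaches 0.001 (cap 20; the reference survey stopped at 14).
  Training is deterministic given the seed. Network inputs default to the
  same five bands as the regression; the source text is self-contradictory
  on this point and the consistent reading is adopted.
* Validation relative error divides by the *inverted* value; this is the
  convention under which the reference verification rows are reproducible
  (two of the ten printed cells differ by up to 0.02 percentage points
  because the source evidently used unrounded inversions).
* Grading errors on values outside [0, 1]; grade and change areas are
  conserved exactly by construction and asserted in tests.
* All randomness flows from explicit integer seeds; scenes are
  bit-identical across runs for a fixed seed.

## Problem sizes

The bundled analyses and tests run scenes of 24--128 pixels per side: a
128 x 128 scene at 10 m (about 164 ha) matches the ~1500 ha reserve scale
the workflow is aimed at while keeping every stage fast enough to iterate
freely. Soil sampling uses 10 training and 10 validation points, the
design of the original campaign.

## Known limitations

* The synthetic scenes cannot reproduce the published raster statistics
  (mean RSEI, loadings, AOD and temperature ranges) because those depend
  on the unavailable satellite imagery; the reproducible quantities are
  the table arithmetic and the parameter-recovery properties.
* The generator's endmember reflectances are implementation defaults: the
  source gives no quantitative description of the study area's spectra.
* Only the wetness tasseled cap component is implemented (the composite
  uses no brightness/greenness components), and only the single-channel
  LST algorithm (no split-window variants).
* The lookup-table excerpt shipped with the package covers four AOD
  levels; full-grid behaviour is exercised with the synthetic surrogate
  table.
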