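---
title: "Methods: from prostate histology microstructure to diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from prostate histology microstructure to diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histodiff)
```

histodiff connects two length scales of prostate tissue measurement: the
micrometre scale of stained histology sections and the millimetre scale of
diffusion-weighted MRI (DWI). It quantifies tissue microstructure from RGB
histology images (cellularity and luminal-fraction maps), simulates water
diffusion inside the segmented tissue to produce a simulated apparent
diffusion coefficient (sADC), and fits a stereological biophysical model
that relates the MRI-measured ADC to cellularity. This vignette documents
the models, the tunable parameters, the numerical choices, and the limits
of what the synthetic validation can show.

## The biophysical model

An imaging voxel is modelled as two compartments: impermeable
non-diffusing volumes (one per cell, mean cross-sectional area
$\bar{A}_n$, in $\mu m^2$) bathed in a fluid of diffusivity $D_0$
(mm$^2$/s), with no exchange between compartments. A histology section is
treated as a thin cross-section of the voxel. The area fraction of
diffusing space in a section with cellularity $C$ (cells/mm$^2$) is

$$\varepsilon_2 = 1 - \bar{A}_n C,$$

and by the stereological argument — integrating area fractions through
the voxel thickness — the volume fraction of diffusing fluid is
approximated by the section's area fraction, $\varepsilon_3 \approx
\varepsilon_2$. This requires the section's cellularity to stand in for
the through-plane average ($\bar{C} \approx C$), which the package
accepts as stated; no through-plane averaging is implemented.

A tortuosity power law relates the diffusing-space fraction to the
measured ADC:

$$\varepsilon^{\tau} = \mathrm{ADC} / D_0,$$

where the tortuosity exponent $\tau$ captures how strongly the shape of
the obstructed medium impedes water. Composing the two gives the forward
model $\mathrm{ADC} = D_0 (1 - \bar{A}_n C)^{\tau}$ and its inverse

$$C = \frac{1}{\bar{A}_n}\left(1 - (\mathrm{ADC}/D_0)^{1/\tau}\right).$$

**Exponent convention.** A printed form of the inverse with exponent
$1/(2\tau)$ circulates; it is *not* the algebraic inverse of the
composed forward model above. `cellularity_from_adc()` defaults to the
self-consistent $1/\tau$ (so forward and inverse compose to the identity
to machine precision, which the test suite asserts) and exposes the
$1/(2\tau)$ variant behind `exponent = "printed"`. The two are never
silently mixed.

## Cellularity maps and threshold calibration

RGB images are converted to the lightness channel $L$ of CIELAB (sRGB
primaries, D65 white point, via `grDevices::convertColor`); pixels with
$L < t$ are classified as stained nuclei. The mask is tiled into square
subregions (default 500 px of 0.23 µm, i.e. 115 µm — note that the often
quoted "0.115 mm$^2$ resolution" is read as a 0.115 mm side length; the
area is 0.0132 mm$^2$). Within each subregion the estimated nucleus
count is segmented area divided by the mean nucleus cross-sectional area
(default 41.29 µm$^2$), and the map value is that count per subregion
area, in cells/mm$^2$. Partial edge subregions are dropped.

The threshold is calibrated against a manually counted grid
(`labeled_grid()`, reference layout 4 × 4 subregions of 500 px). Eight
disjoint neighbouring pairs — paired row-wise in raster order, so no
subregion is reused — are held out in turn; on the remaining 14
subregions the threshold minimizing the sum of absolute count errors is
found, and the held-out pair's mean relative count error is that fold's
cross-validation score (CVS). The reported threshold is the mean of the
fold thresholds. Because the objective is piecewise constant in $t$
(counts change only when a pixel crosses the threshold),
gradient-based optimization is ill-posed; the package uses a coarse grid
(step 0.5 L) followed by golden-section refinement of the same
objective, keeping whichever attains the lower value. Subregions with a
manual count of zero contribute relative errors with denominator
$\max(\mathrm{count}, 1)$; an all-zero grid is rejected as degenerate.

Whether partially visible nuclei at subregion borders are counted is
ambiguous in manual protocols; the synthetic labeller uses the centroid
rule (a nucleus belongs to the subregion containing its centre).

## Luminal-fraction maps

Lumina are unstained and appear near-white. Pixels are clustered by
k-means (k = 6 by default) on the CIELAB chroma channels (A, B); for
large images the centres are fitted on a random sample of up to 2 × 10⁵
pixels (5 restarts, lowest within-cluster sum of squares) and all pixels
are assigned to the nearest centre. Cluster selection was manual in the
original workflow; the default here is automatic — clusters whose Lab
centre has $L > 85$ and chroma $< 20$ — with explicit indices and
"complement" clusters (those identifying the lumen exterior) available
in `lumen_config()`. The selected mask is morphologically closed with a
disk (radius 5 px default), connected components are labelled
(8-connectivity), and components outside [50, 10⁷] px are discarded;
all three numbers are exposed because no reference values exist. The
λ map reports the percentage of luminal pixels per grid cell.

The λ grid defaults to the cellularity grid (500 px) so the three maps
share a geometry for joint analysis; the much finer 20 px grid
(4.6 µm at full resolution) is available via `grid_px` but conflicts
with the other maps' resolution, so it is not the default.

## The random-walk sADC simulator

Within each map subregion, the diffusing space is the complement of the
nucleus mask. $N_p$ walkers start uniformly over free-pixel centres;
each of $N_t$ time increments proposes an isotropic Gaussian
displacement with per-component variance $\sigma^2 = 2 D_f T / N_t$.
A proposal landing on a non-free pixel is rejected and the particle
keeps its position for that increment (no re-draw — the pseudocode
convention is followed literally). When a proposal leaves the field of
view, membership is evaluated on the periodically tessellated mask
(positions are wrapped only for the lookup; true displacement keeps
accumulating). Membership lookup is nearest-pixel: the continuous
position in µm is floored to a pixel index, modulo the mask dimensions.

Defaults are $N_p = 5000$, $N_t = 2630$, $T = 8.67$ ms (matched to the
DWI protocol's diffusion time) and $D_f = 3.0 \times 10^{-3}$ mm$^2$/s
(free water at 37 °C). A figure-caption variant of these settings
(10,000 particles, 1,000 × 10 µs steps) is internally inconsistent with
$T$ and is not used. The diffusivity estimate is the ordinary
least-squares slope of the mean-squared-displacement curve over all
recorded points divided by 4 (the 2D Einstein relation; the simulation
and masks are two-dimensional). The free intercept absorbs short-time
boundary-layer curvature. $\sigma^2$ is interpreted as the
*per-component* variance of the isotropic step, so the free-space MSD
slope is $4 D_f$; the test suite pins this convention by recovering
$D_f$ within 2% in an unobstructed domain.

Note that under tessellation a lone free pixel is effectively a lattice
of free sites: walkers hop between periodic images when $\sigma$ is
comparable to the field of view, and the MSD keeps growing. True
confinement tests use `periodic = FALSE`. A warning is emitted when
$\sigma$ exceeds the mask extent.

The tortuosity sweep validates the power law in 2D: random-disc domains
(disc radius defaulting to the equivalent circular radius of
$\bar{A}_n$, 4.66 µm) are generated across a series of free-space
fractions, and $\log \mathrm{sADC}$ is regressed on $\log \varepsilon$
using each domain's *realized* free fraction. The fitted slope is
$\tau$, the intercept $\log D_0$.

## ADC fitting and ROI statistics

Multi-direction DWI signals are averaged arithmetically in the signal
domain (not the log domain — the two differ under noise) and fitted with
the monoexponential model $S(b) = S(0) e^{-b\,\mathrm{ADC}}$ on the
acquisition grid $b = 0, 100, 200, 400, 800$ s/mm$^2$. The default fit
is log-linear least squares, which inverts noiseless data exactly; a
signal-domain nonlinear refinement (`method = "nls"`) is available since
the two weight noisy high-b points differently. Negative fitted ADCs are
clipped to zero and flagged. ROI values are arithmetic means of
non-missing map values under the mask.

## Model fitting, uncertainty, and cross-validation

`fit_cellularity_model()` fits the inverse model to ROI-level
(ADC, cellularity) pairs by multi-start nonlinear least squares
(Levenberg–Marquardt trust-region solver, 5 starts crossing a D0 grid
above $\max(\mathrm{ADC})$ with a $\tau$ grid; bounds
$D_0 > \max(\mathrm{ADC})$, $\bar{A}_n > 0$, $\tau > 0$). Confidence
intervals are nonparametric bootstrap percentiles over ROIs (2000
resamples by default, seeded).

Because ADC enters the regression as a noisy predictor, plain NLS
carries an errors-in-variables bias — with a few percent of
multiplicative noise on both coordinates, $\tau$ is systematically
overestimated by roughly its own noise-driven sd. `method = "eiv"`
refines the NLS solution with an orthogonal-distance criterion (equal
relative noise assumed on both axes), which removes the bias. Even so,
$\tau$ is the weakly identified parameter of this model: at 50 ROIs and
3% noise its sampling sd is on the order of 13%, irrespective of the
estimator, while $D_0$ is recovered to ~1–2%. The parameter-recovery
tests assert medians accordingly (10% for $D_0$ and $\bar{A}_n$, 15%
for $\tau$).

Leave-one-animal-out cross-validation refits the chosen model without
each animal's ROIs and predicts the held-out ROIs from their ADC.
"Median deviation" is operationalized as the median of
$|pred - obs| / obs$ over held-out ROIs (no standard definition
exists), and NRMSE is RMSE divided by the observed range, which makes
it invariant to affine unit rescaling of the target.

## The two-component linear mixture model

Per-pixel triples (cellularity, luminal fraction, sADC) on a shared map
grid are modelled as a 2-component mixture of Gaussian linear
regressions with sADC as the response and both histology covariates as
predictors — the joint form is this package's choice; the original
analysis is ambiguous about whether each scatter axis was fitted
separately, so the formulation is recorded in the output metadata.
EM runs from 10 random soft initializations; a restart degenerates if a
component's weight falls below $1/n$ or its residual sd collapses, and
the best non-degenerate log-likelihood wins. Convergence is a relative
log-likelihood change below $10^{-8}$ or 500 iterations; the trace is
stored and tested for monotonicity. Components are ordered by the mean
luminal fraction of their hard assignments, so "C1" is reproducibly the
tissue compartment and "C2" the lumen compartment.

## The synthetic-tissue generator

`generate_tissue()` emulates the statistical structure the pipeline
assumes in HES-stained sections: dark blue-purple elliptical nuclei
(truncated-normal areas, mean 41.29 µm$^2$) on pale pink stroma with
near-white luminal blobs, at 0.23 µm/pixel, plus per-channel Gaussian
colour noise. The planted nucleus count is Poisson with mean
(target cellularity × area); nuclei are non-overlapping (rejection
sampling with a retry cap that reports the achievable density on
failure) and disjoint from lumina; lumina are a Gaussian-smoothed noise
field thresholded at the exact target area fraction, which produces
irregular gland-like shapes. All randomness flows from the spec's seed.

Two generator parameters are modelling choices with no reference value:
the nucleus-area SD (8 µm$^2$, about 20% CV, a typical spread for
epithelial nuclei — only the SE of the mean, 0.42 µm$^2$ over 1,110
nuclei, is known) and the eccentricity range (0.3–0.8).

**What synthetic validation does not show.** The generator reproduces
geometry and first-order colour statistics, not stain physics: there is
no colour deconvolution, no chromatin texture, no touching-nuclei
clumps, no out-of-focus blur, and stroma is homogeneous. Passing
recovery tests therefore demonstrates correctness of the estimators
under the model's own assumptions, not robustness to real staining
variability. In particular, in synthetic tissue the
sADC–(cellularity, λ) relation forms a *single* plane — lumen-rich
pixels sit on the tissue plane's extrapolation and the two covariates
are strongly collinear — so a 2-component mixture fitted to
generator-derived maps splits along residual variance rather than
biology. The mixture machinery is therefore validated on data with
genuinely planted two-compartment structure (including semi-synthetic
maps whose sADC is keyed to the ground-truth lumen label); the
two-compartment finding itself is a property of real tissue that the
generator does not emulate.

The ROI-cohort generator draws cellularity uniformly, computes ADC
through the forward model, applies multiplicative Gaussian noise of a
chosen CV to both coordinates, and assigns animals round-robin for
grouped cross-validation; its luminal-fraction and sADC columns follow
the package's reference ROI-level linear relations.

## Numerical and I/O conventions

Degenerate inputs are contracts, not surprises: subregions with no free
space yield missing (NA) map values, never zero; empty ROI masks,
all-zero manual counts, signals ≤ 0 in log fits, cellularity above the
packing limit $1/\bar{A}_n$, and ADC > $D_0$ all raise errors naming
the cause. Maps are written as CSV (full double precision, missing as
empty cells) with a JSON sidecar carrying quantity, units, grid
geometry, origin and seed; reading without the sidecar is an error —
physical pixel size is never guessed. The TIFF export is a scaled
encoding (values divided by a recorded scale to fit the writer's [0,1]
range) intended for viewing; the CSV is the lossless round trip.

Test and validation problem sizes are deliberately modest — synthetic
slides of 400–2000 px, sweeps at 1000–1500 walkers and a few hundred
steps, bootstraps of 100–500 resamples — chosen so the full suite
exercises every claim at desk scale; the estimators themselves carry no
size limits beyond memory.
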