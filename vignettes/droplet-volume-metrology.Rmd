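---
title: "Droplet volume metrology for digital PCR: models, parameters and design choices"
author: "dropMetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet volume metrology for digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropMetrics)
```

## The measurement problem

Digital PCR partitions a sample into thousands of droplets, amplifies to
end point, and counts how many droplets light up.  If targets are randomly
distributed, the number of copies per droplet is Poisson, so the positive
fraction $H/C$ determines the mean occupancy
$\lambda = -\ln(1 - H/C)$ and the copy-number concentration of the
undiluted sample is

$$T_c \;=\; D_f \times \frac{1}{C\,V_d} \times
  \frac{\log\!\left(1 - H/C\right)}{\log\!\left(1 - 1/C\right)},$$

with $C$ analysed droplets, $H$ positive droplets, droplet volume $V_d$
(in µL inside the formula; the package accepts nL at every interface and
converts internally, because nL is the unit volumes are reported in) and
final dilution factor $D_f$.  The finite-$C$ log ratio differs from the
continuous form $-\ln(1-H/C)/V_d$ by less than 0.01 % for
$C \ge 10^4$ (since $\ln(1-1/C) \approx -1/C$), and the package tests
assert exactly that.

Everything in the formula is counted or weighed except $V_d$ — the volume
of a single droplet, which enters as a divisor.  Instrument software
assumes a fixed $V_d$; if the droplet generator actually produces droplets,
say, 8 % smaller than assumed, every absolute concentration it reports is
8 % low.  That error is invisible in ratio measurements and systematic in
absolute ones, which is why a metrological workflow re-measures $V_d$ by
optical microscopy and why certified reference materials (CRMs) are the
instrument-independent arbiter.

The package implements this whole chain: droplet sizing from brightfield
micrographs, gravimetric dilution factors, concentration conversion,
intermediate-precision uncertainty, and CRM bias testing, plus a
synthetic-data module that makes every step testable against known truth.

## Gravimetric dilution

Pipetted volumes are nominal; weighed masses are traceable.  The assay
dilution factor is computed from masses and densities,

$$D_a = \frac{m_{\mathrm{DNA}}/\delta_{\mathrm{DNA}} +
  m_{\mathrm{premix}}/\delta_{\mathrm{premix}}}
  {m_{\mathrm{DNA}}/\delta_{\mathrm{DNA}}}, \qquad D_f = D_s \times D_a,$$

with the premix density itself determined by repeated weighing of a fixed
volume (`premixDensity()`).  Typical values: a 33.6 µL sample (density
1.0000 g/mL) mixed with 62.4 µL premix (1.03532 g/mL) gives
$D_a = 2.857$.

## Droplet sizing from brightfield images

### Segmentation pipeline

`segmentDroplets()` runs, in order: Sobel gradient magnitude ("find
edges"); thresholding of the gradient; despeckling; hole filling; an
optional one-pixel erosion; optional watershed separation of touching
droplets on the distance transform; border exclusion; minimum-area
filtering.  The parameters that matter:

* **Threshold** (`threshold_method = "otsu"`, default).  The gradient
  histogram of a droplet image is trimodal: noise, the weaker
  background-to-rim edge, and the stronger rim-to-interior edge.  A plain
  Otsu threshold tends to fall *between* the two edge populations and
  clips the weak-response arcs of each rim (edge response varies with
  local boundary orientation), which biased measured diameters by about
  −1 % in development experiments.  The package therefore uses Otsu as the
  strong threshold of a *hysteresis* rule: pixels above
  `hysteresis_low_frac` (default 0.3) of the Otsu value are kept when
  8-connected to a pixel above it.  Rims survive in full; isolated noise
  responses, which lack a strong seed, do not.  A `fixed` threshold (grey
  levels) is available for exact reproducibility.
* **Despeckle** (`despeckle_radius_px = 1`): the classical 3×3 median.  On
  a binary image a median filter is exactly a majority vote over the
  window, so it is computed by box filtering — identical output, about
  30× faster on megapixel fields.
* **Erosion after hole filling** (`erode_after_fill = TRUE`).  A 3×3
  gradient operator responds one pixel on either side of a step edge, so
  the thresholded-and-filled object is the true object dilated by one
  pixel — a systematic +2 px on every diameter, which at 1 µm/px is a
  +1.7 % volume error on a 117 µm droplet.  A single 3×3 erosion undoes
  that dilation exactly for convex objects.  With it, measured mean
  diameters on synthetic fields are within 0.01–0.5 % of ground truth;
  without it they are biased high by the full two pixels.
* **Watershed** (`ws_tolerance_px = 2`): markers are the distance-map
  maxima; two maxima merge unless separated by a saddle deeper than the
  tolerance.  Two pixels is deep enough to split droplets whose centres
  sit at 0.95–1.0× the sum of radii, and shallow enough not to shatter
  single droplets, whose distance maps are smooth cones.
* **Minimum area** (`minAreaForScale()`): defaults to the pixel area of a
  30 µm disk, mirroring the droplet reader's own rejection of satellite
  droplets, so the sizing statistics describe the droplets that are
  actually counted.

### Measurement

`measureDroplets()` fits an ellipse to each region from second-order
moments (semi-axes $2\sqrt{\lambda_i}$ of the covariance eigenvalues, the
moments of a uniform ellipse), and reports the **area-equivalent
diameter** $d = \sqrt{\text{major} \times \text{minor}}$ — the diameter of
the circle whose area equals the fitted ellipse's.  The **Feret
(caliper) diameters** are computed by rotating calipers on the convex hull
at 0.5° resolution, with no hull smoothing: caliper widths include the
+1 px pixel extent, so a digital square of side $s$ measures
$s$ / $s\sqrt2$.  Mean Feret is never below the area-equivalent diameter
for convex regions (they coincide for disks); staircase protrusions on
digitised boundaries inflate Feret, which is precisely why the
area-equivalent diameter is the one cubed into a volume.  Watershed-cut
regions are not convex, so that ordering is asserted only on isolated
droplets.

Volumes assume sphericity, $V = (\pi/6)d^3 \times 10^{-6}$ nL (surface
tension keeps emulsion droplets spherical to well under the other error
terms).  Regions under 5 px are skipped — a moment fit on fewer pixels is
noise.

The pixel scale comes from a stage-grid image (`calibrateScale()`): dark
lines are detected by Otsu on the inverted image, the line direction from
the principal axis of the largest line component, and spacing measured by
projecting line centroids on the line normal — so a rotated grid needs no
separate cosine correction.  The relative uncertainty is the standard
error of the gap widths; a certified graticule typically contributes
about 0.15 %.

### Averaging volumes across days

`averageDropletVolume()` offers three conventions.  Working from printed
per-day summaries $(\bar d, s)$, the population mean volume is the
second-moment correction
$E[(\pi/6)d^3] \approx (\pi/6)(\bar d^3 + 3\bar d s^2)$ (the skewness term
is negligible for near-symmetric diameter distributions); the
`moment_corrected` mode averages that over days and is the default,
because it is the only convention computable from summary tables alone
and it reproduces published grand averages to the printed 3 decimals.
`pooled_droplets` (droplet-count-weighted) and `mean_of_day_means`
(unweighted) differ from it only in the third decimal on real data; the
published tables do not state which convention was used, so all three are
exposed.

## Uncertainty of the grand mean

A balanced day × replicate design is analysed as a one-way random-effects
ANOVA (`intermediatePrecision()`): $s_r^2 = MS_{within}$,
$s_b^2 = \max(0, (MS_{between} - MS_{within})/n)$, and

$$u^2(\bar{\bar T}) = \frac{s_b^2}{p} + \frac{s_r^2}{pn}, \qquad
  U = 2u \;(k = 2).$$

Negative component estimates are truncated at zero and flagged.  Two
statistical notes.  First, with $p = 3$ days the between-day estimate has
2 degrees of freedom; on the *standard-deviation* scale the
truncation-plus-square-root combination makes its expectation about 16 %
low no matter how it is implemented, while on the *variance* scale the
estimator is essentially unbiased (+1 % in a 20 000-run simulation) —
recovery tests therefore assert variance components.  Second,
reconstructing the ANOVA from printed day means and sds
(`intermediatePrecisionFromSummaries()`) on the packaged 3 × 8 dataset
gives $U \approx 160$ cp/µL where the published table prints
$\pm 200$; the published value may include components beyond the two the
stated combination contains, so the package asserts the grand mean
(9454 cp/µL) exactly and the formula only on synthetic data.

## Bias against certified values

`assessBias()` declares a significant bias (95 % confidence) when
$\Delta_m = |\text{certified} - \text{mean}|$ strictly exceeds the
combined expanded uncertainty $U_\Delta$.  Published comparison tables of
this kind are not always internally consistent: the table this package
reproduces defines $u_m = sd/\sqrt n$ in its footnote, yet its printed
$u_m$ and $U_\Delta$ columns equal $\sqrt{(sd/2)^2 + (U_{CRM}/2)^2}$ and
$\sqrt{sd^2 + U_{CRM}^2}$ for every row.  Both conventions are
implemented: `as_printed` (the default, which reproduces every printed
row and verdict) and `footnote` (the stated definition, whose $U_\Delta$
is never larger for $n \ge 4$, so it never declares fewer biases).  The
discrepancy is surfaced by exposing both, not silently resolved.
Display rounding is integers for cp/µL columns and percents; full
precision is retained internally.

## What the synthetic generator emulates — and what it does not

`renderMonolayer()` draws near-circular droplets with normally
distributed diameters (defaults: 117.0 µm mean, 2.2 µm sd — the middle of
the 1.4–3.2 µm range seen across real measurement days) as bright disks
with a 2 px darker rim on a noisy mid-grey background at 1 µm/px, in
2048 × 1536 px fields of 75 droplets; eight fields give the ~600 droplets
per day of the real sizing protocol.  Touching droplets (centre distance
0.95–1.0× the sum of radii) exercise the watershed without merging
interiors; border-crossing droplets exercise edge exclusion; 20 µm
satellites exercise the minimum-area filter.  The day effect in
`simulatePartitionCounts()` is multiplicative log-normal with unit mean
(keeping concentrations positive), and positives are drawn binomially
with $p = 1 - e^{-\lambda}$.

Deliberate non-goals: no optics (defocus, point-spread, vignetting), no
fluorescence crosstalk or "rain" of intermediate amplitudes, no
close-packed monolayer geometry — placement is random sequential
adsorption, which cannot reach the ~80 % coverage of a real emulsion
monolayer, so synthetic fields hold fewer droplets per field than real
ones (droplets per *day* is the matched quantity).  Consequently, passing
tests demonstrate that the *algorithms* are unbiased on images whose
contrast model they assume; they do not certify performance on real
micrographs with uneven illumination or focus gradients, where the
fixed-threshold option and the scale calibration become the operator's
responsibility.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state (`withr::with_seed`); identical specs give
  bit-identical images, counts and reports.
* Pixel coordinates are 0-based; region areas count whole pixels;
  connectivity is 8 (for the filled disk-like masks this pipeline
  produces, 4- and 8-connectivity give identical components).
* `H = C` (all droplets positive) is an error, not infinity: the assay
  must be diluted, and the error says so.
* The per-well confidence interval (`concentrationCI()`) is a Wilson
  score interval on $H/C$ mapped through the monotone concentration
  transform; it is plumbing for plots and sanity checks, not part of the
  published uncertainty budget, and no published value is asserted
  against it.
* Problem sizes in the test suite were chosen as the smallest that hold
  the statistical tolerances with comfortable margins: 3 days × 8 fields
  × 75 droplets for diameter recovery (±0.5 %), 100 replicate wells per
  concentration for estimator recovery (±3 SE over 10–10⁶ cp/µL), and
  500 simulated 3 × 8 designs for variance-component recovery (±15 %).

## Worked numbers

```{r}
# printed per-day diameters -> volumes -> 3-day average
days <- dropletDaySummaries()
round(sphereVolumeNl(days$mean_diameter_um), 3)
round(averageDropletVolume(days, "moment_corrected"), 3)

# the software's assumed volume vs the measured one
round(100 * (0.91 - averageDropletVolume(days)) / 0.91)

# grand mean and its intermediate-precision uncertainty
intermediatePrecisionFromSummaries(days$conc_mean_cp_per_ul,
                                   days$conc_sd_cp_per_ul,
                                   n = days$n_replicates[1])

# CRM comparison at the assumed 0.91 nL volume
biasTable(crmReferenceValues(), ddpcrMeasurementSummaries())[,
    c("level_id", "certified_value", "mean", "delta_m", "U_delta",
      "significant")]
```

## Known limitations

Sizing is 2D with a sphericity assumption; systematic non-sphericity
would need a type-B term the package does not model.  The scale
calibration assumes straight, parallel grid lines.  The bias test uses
$k = 2$ throughout, with no Welch–Satterthwaite refinement of the
coverage factor.  The amplitude model is two well-separated Gaussians —
sufficient for threshold-classification logic, silent on rain.
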