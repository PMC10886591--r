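---
title: "Characterizing fibrin clots from turbidity, scattering and network images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing fibrin clots from turbidity, scattering and network images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotquant)
```

## The measurement problem

Fibrin — the polymer scaffold of a blood clot — assembles when thrombin
cleaves fibrinogen into monomers that polymerize into protofibrils and then
laterally aggregate into fibers. How thick those fibers are, how dense the
network is, and how fast it forms all depend on the fibrinogen and activator
(thrombin or tissue factor) concentrations, and all of them have clinical
correlates. `clotquant` implements the desk side of a microplate
characterization study: three independent measurement streams (kinetic
turbidity, multi-wavelength end-point turbidimetry, fluorescence network
images) are each reduced to interpretable parameters, which are then
regressed on the concentration design.

Because no raw data accompany the published study this pipeline emulates,
the package ships a first-class synthetic-data generator with exact ground
truth. Every estimator in the package is validated against that truth; the
published values enter only as *inputs* (slopes, table anchors, the printed
regression coefficients) that define the generator's default study.

## From absorbance to turbidity

Plate readers report optical density. With the well's background subtracted,
turbidity in natural-log units per cm of path is

$$\tau = \frac{A\,\ln 10}{x},$$

where the optical path length $x$ is not known a priori in a microplate: it
depends on fill volume. It is measured per well from the near-infrared water
absorbance step, $x = (A_{977} - A_{900})/k_\mathrm{water}$, with
$k_\mathrm{water} = 0.18\ \mathrm{cm^{-1}}$ by default (the constant is
instrument-dependent and configurable; the source study does not print its
value). The background default is a dedicated blank well when one is
present. Estimating background from a well's own first readings is also
supported, but it is not the default for kinetics: a clotting curve is
already above its asymptote at the first read, so per-well initial readings
systematically over-subtract (by about 6% of plateau at the mid-grid
parameterization).

## Clotting kinetics

Three parameters summarize a turbidity time course sampled every 15 s for
1 h: the **maximum turbidity** (plateau, a fiber-mass/thickness proxy), the
**rate of clot formation** (maximal slope), and the **lag phase**
(protofibril-formation time before measurable turbidity rise).

All three share one centered moving-average smoother (default 5 points,
60 s support). The rate is the maximum over all 5-point windows of the
least-squares slope of the smoothed curve. Smoothing *before* taking the
window maximum matters with noisy data: the maximum over ~240 windows of
noisy slopes is upward-biased by selection, which then propagates into the
lag. With smoothing, read noise of 0.002 OD leaves a residual rate bias of
a few percent; without it the bias exceeds 10%.

The default lag convention is the tangent method: the maximal-slope tangent
is intersected with the baseline. For a background-subtracted curve the
baseline is 0 (the asymptote), which makes the estimator exact on logistic
curves — for $\tau(t) = P/(1+e^{-k(t-t_0)})$ the tangent at $t_0$ meets zero
at exactly $t_0 - 2/k$. A threshold convention (first time above baseline +
threshold) is provided as an alternative since conventions differ between
laboratories. A computed lag earlier than the first reading by more than
half a sampling interval is reported *censored* (rendered as a dash in the
tables, matching how such wells are reported in practice); estimates within
half a sample of the start are clamped to the first reading. A flat curve
has an undefined lag, which is flagged rather than censored.

Estimator limits: when the logistic transition ($4/k$) is comparable to the
combined smoothing-plus-window support (120 s), the windowed slope
underestimates the true maximal derivative — about 7% low at the fastest
plasma-like magnitudes ($P k/4 \approx 0.06\ \mathrm{cm^{-1}/s}$), under 1%
at the purified-fibrinogen table magnitudes. The tests assert 2% recovery
where the method is in its validity regime and 10% at the fast extreme.

## Fiber dimensions from wavelength-dependent turbidimetry

A suspension of long, thin, rigid rods scatters with

$$\tau(\lambda) = K_1\, c\, \mu\, \lambda^{-3}
  \left(1 - K_2 \frac{r^2}{\lambda^2}\right),
\qquad K_1 = \frac{88}{15}\,\pi^3\, n_s \left(\frac{dn}{dc}\right)^2
  \frac{1}{N_A},$$

where $c$ is fibrin mass concentration (g/cm³), $\mu$ the mass–length ratio
(Da/cm, proportional to protofibrils per cross-section) and $r$ the fiber
radius. Two classic linearizations invert a 500–800 nm spectrum:

* **Yeromonahos:** regress $\tau\lambda^5$ on $\lambda^2$; the model above
  is *exactly* linear in these variables, so $\hat\mu = a/(K_1 c)$ and
  $\hat r^2 = -b/(a K_2)$ recover the generating values to numerical
  precision on noiseless spectra (the package's round-trip acceptance
  property, which holds for any $K_2 > 0$ and any grid of ≥ 3 wavelengths).
* **Carr–Hermans:** regress $c/(\tau\lambda^3)$ on $1/\lambda^2$. This
  linearizes $(1-u)^{-1} \approx 1+u$, truncating a positive series, so its
  fitted slope — and diameter — is inflated for thick fibers. The package
  verifies the resulting ordering $\hat d_{CH} \ge \hat d_{Y}$, converging
  as $r \to 0$, which reproduces the qualitative method disagreement the
  study observed (Carr–Hermans largest, differences growing with fiber
  thickness).

Uncertainties on $\mu$, $r$ and $d = 2r$ come from the fit covariance by the
delta method and vanish as spectral noise vanishes. Fits with a
non-negative intercept (Yeromonahos) report $\mu$ with a radius-failure
flag; spectra with in-band absorbance above 1 OD are flagged for multiple
scattering, which the model does not correct.

**Constants.** $n_s = 1.333$ and $dn/dc = 0.186\ \mathrm{cm^3/g}$ are the
standard aqueous-fibrin values; the radius-correction coefficient defaults
to $K_2 = (184/154)\pi^2$ for both methods. Published treatments differ in
whether $\lambda$ is the vacuum or in-medium wavelength and whether $n_s$
enters the correction term; both conventions are implemented. The default
is the vacuum convention: with the in-medium convention at the same $K_2$,
the correction term exceeds 1 (model breakdown) for radii near 120 nm at
500 nm — inside the fiber-size range this study design covers. All
constants live in one registry (`scattering_constants()`) and every
estimate records which convention produced it; the round-trip property is
deliberately constants-independent.

**Domain limits are surfaced, not hidden.** For the default plasma trend
coefficients, fibers at high fibrinogen reach ~460 nm diameter, where
$K_2 r^2/\lambda^2 \ge 1$: the forward model refuses to generate such
spectra, the simulator records those wells as scan failures, and the
pipeline completes with partial outputs and a nonzero status. That mirrors
the physical statement that turbidimetric inversion becomes unreliable for
thick fibers.

## Network image morphometry

The published measurements were manual (Fiji line tool). The package
substitutes deterministic morphological definitions, documented as an
emulation and validated only against synthetic truth:

* **Percent area covered** — foreground fraction of the binarized image
  (Otsu by default, fixed threshold as fallback for degenerate images).
* **Pore size** — per connected background region not touching the border
  (border pores are censored by the field of view), the diameter of the
  largest inscribed circle, i.e. twice the maximum of the Euclidean
  distance transform. For a drawn circular or square pore this equals the
  drawn diameter/side to within a pixel.
* **Fiber segment length** — Zhang–Suen skeletonization, split at branch
  points (≥ 3 skeleton neighbors), path length with diagonal steps weighted
  $\sqrt 2$. Thinning erodes about half the fiber width from each free end,
  so the distance-transform value at each true endpoint is added back;
  spur segments shorter than 3 px are discarded. A drawn 100-px bar is
  recovered within ~1%.

These definitions are pixel-size equivariant and stable under 90°
rotation (< 3% on 256-px fields; small sparse fields show discreteness
effects of a few percent). They measure *all* qualifying objects, unlike
the manual protocol whose per-image sampling is unstated — one reason the
package never claims to reproduce the manual numbers, only the trends.

## Outlier screening and trend models

Replicate groups are screened with the iterative two-sided Grubbs test at
$\alpha = 0.05$: remove the most extreme value while
$G = \max_i |x_i - \bar x| / s$ exceeds
$\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$, $t$ the upper $\alpha/(2n)$
t-quantile on $n-2$ df. Zero-variance groups are untouched, and removal is
capped at 20% of a group (at least one candidate) to avoid pathological
stripping — the cap is a package choice where the source protocol is
silent.

Trend fitting follows the reported convention of operating on means:
`simple_regression()` averages the response per concentration level before
ordinary least squares, and `multiple_regression()` fits
$y = \beta_0 + \beta_{Fg}[\mathrm{Fg}] + \beta_{Act}[\mathrm{Act}]$ on
per-condition means (per-observation fitting is available). Thrombin and
tissue-factor designs are never pooled into one regression — different
units and mechanisms. A rank-deficient design (one concentration constant)
raises an instructive error, and the pipeline falls back to a simple
regression on the varying axis with a logged notice. The sign-trend table
reduces each model to coefficient signs and flags responses where the
purified and plasma signs disagree (lag time versus fibrinogen is the
notable case: positive for purified clots, negative for plasma).

## The synthetic study and what passing tests mean

`simulate_structure()` draws each parameter from a linear surface
anchored at the reference condition (2.7 mg/mL fibrinogen, 0.1 U/mL
thrombin) with per-parameter Gaussian noise; `simulate_kinetics()` maps
(plateau, rate, lag) bijectively onto a logistic
($P = $ plateau, $k = 4\,\mathrm{rate}/P$, $t_0 = \mathrm{lag} + 2/k$)
emitted as absorbance with additive read noise; `simulate_scan()` couples
the mass–length ratio to the radius by the homogeneous-cylinder rule
$\mu \propto r^2$ (fixed-$\mu$ mode available) and multiplies the rigid-rod
spectrum by mean-one lognormal noise; `render_network_image()` draws random
straight segments until a target area fraction is reached and returns the
exact truth mask. One seed determines the entire dataset.

Default slopes are the published simple-regression slopes (diameter from
electron microscopy; pore, area, length from confocal measurements;
kinetic slopes refit from the published tables). Anchors for structural
parameters are not published; they were chosen once so every parameter
stays positive over the full factorial grid (for instance, 130 nm purified
diameter at the reference condition) and are labeled synthetic
conveniences. The plasma kinetic anchor uses the published fibrinogen-series
value because the thrombin-series value would drive the linear surface
negative at low fibrinogen. Noise SDs are likewise unpublished; they were
set by a power calculation so that the design's own acceptance surface —
refitted multiple-regression coefficients within 10% of the generating
slopes on per-condition means with triplicate wells — holds with wide
margin (≥ 3.8 SE on every coefficient): 5 nm diameter, 0.15 µm pore, 0.5%
area, 0.25 µm length, 5 s lag, 5 × 10⁻⁴ cm⁻¹/s rate, 0.15 cm⁻¹ plateau,
0.002 OD read noise. These magnitudes are what the generated-data metadata
declare; real replicate scatter (especially plasma lag, with published SDs
up to ~36 s) is larger, so passing the recovery tests demonstrates estimator
correctness, not that real data of this design would constrain the
coefficients this tightly.

The generated lag can legitimately be negative (clotting before the first
read); the kinetic stream then produces curves whose extracted lag is
censored, reproducing the dashes in the published tables. Censored lags are
excluded from the lag regressions.

What the generator does **not** emulate: mechanistic polymerization
(fibrinopeptide release, protofibril growth), plasma matrix effects beyond
different trend coefficients, lysis, spatial correlation between the image
and scattering streams of the same well, or wavelength-dependent $dn/dc$.
Conclusions about real plasma data should lean on the sign structure, not
the synthetic effect sizes.

## Numerical choices

* Problem sizes: the default study is 2 sample types × 4 × 4 conditions ×
  3 replicates = 96 wells, 241 time points per trace, 31 analysis
  wavelengths per scan, 256-px rendered images — chosen so a full run
  (simulate, ingest, fit everything, write the bundle) takes a few seconds.
* The regression R² is computed from residual and total sums of squares
  directly (0 when the response is constant).
* IQR summaries use the linear-interpolation quantile convention
  (`type = 7`); SEM of a single value is reported as 0. Normality testing
  is deliberately out of scope; the caller selects mean ± SEM versus
  median ± IQR.
* Rolling-window ties: the first window attaining the maximal slope is
  used; for the symmetric logistic this is the window straddling $t_0$.
* All report files are written with fixed formatting and no timestamps, so
  a seed + config pair reproduces the bundle byte for byte (the manifest
  records the seed and a config hash).
* `%.17g` formatting for the simulated plate files makes the write/read
  round trip lossless at double precision.

## Known limitations

* The manual-measurement emulation is validated against synthetic truth
  only; no claim is made of agreement with line-tool numbers on real
  images.
* Turbidimetric inversions assume single scattering and the rod regime;
  both violations are flagged, not corrected.
* The rate estimator saturates for very fast clots (transition within one
  smoothing window), and the tangent lag inherits some of that bias under
  heavy noise.
* Tissue-factor designs are supported in the condition schema and
  validation, but the default generator varies thrombin; TF levels enter
  in pM and are never mixed with thrombin units in one regression.
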