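---
title: "Methods: mechanistic calibration of scratch assays with the Fisher-Kolmogorov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic calibration of scratch assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A scratch assay wounds a settled cell monolayer with a uniform vertical
scratch and images the re-colonisation of the vacant strip. Because the
initial condition is independent of the vertical coordinate, the
two-dimensional density field can be averaged over y without error, and the
assay is modelled by the one-dimensional Fisher-Kolmogorov (FKPP) equation

$$\frac{\partial C}{\partial t} = D\,\frac{\partial^2 C}{\partial x^2}
  + \lambda\, C \left(1 - \frac{C}{K}\right),$$

for the y-averaged density $C(x,t)$ (cells/µm²) on $0 \le x \le L_x$, with
zero-flux boundaries (the physical monolayer extends beyond the imaged
field, so no net flux crosses the frame edges) and the step initial
condition $C = C_0$ outside the scratch
$[x_c - L_E(0),\, x_c + L_E(0))$ and $C = 0$ inside. All three parameters
are assumed constant in space, time and density. Well behind the wound the
density is spatially uniform, the diffusion term vanishes, and the model
reduces to logistic growth with the closed form
$C(t) = K C_0 / \{C_0 - e^{-\lambda t}(C_0 - K)\}$ — the basis of the
count-based stages of the estimator.

Defaults throughout correspond to a control PC-3 assay: field of view
1970 × 1430 µm, scratch centred at 985 µm, frames every 2 h for 46 h,
$C_0 = 6.84\times10^{-4}$, $K = 1.13\times10^{-3}$ cells/µm²,
$\lambda = 5.07\times10^{-2}$ /h, $D = 132$ µm²/h, initial half-width
300 µm (half-widths of a few hundred µm are typical of mechanical
wound-makers; the value is configurable and every test states its own).

## Numerical scheme

Space is discretised by central differences (δx = 1 µm), time by backward
Euler (δt = 0.1 h). The nonlinear logistic term is linearised by Picard
iteration, lagging **only the quadratic factor**
($\lambda C^{m+1}(1 - C^{p}/K)$): this keeps every inner solve a linear
tridiagonal system, handled by the Thomas algorithm in O(n). Iteration
stops when the max-norm change falls below ε = 10⁻⁶ (density units); a cap
of 100 sweeps (2–3 suffice in practice) turns non-convergence into a
fail-fast error carrying the step and residual. Zero-flux boundaries use
mirrored ghost nodes, which are second-order accurate and make the scheme
exactly mass-conservative under the trapezoid rule when λ = 0 — a property
the tests verify to 10⁻¹² relative. Requested output times are snapped to
the nearest multiple of δt with a warning, since the scheme is fixed-step
by design.

Halving (δx, δt) moves the predicted half-width by under 1 µm and the
density field by about 10⁻³·K over the whole assay, so the default grid is
in the converged regime. Against the closed-form logistic (uniform initial
condition) the solver agrees to about 2 × 10⁻⁷ cells/µm² over 46 h; this
residual is the first-order backward-Euler time error at δt = 0.1 h, not a
solver defect — it halves when δt is halved.

The model half-width is read off a profile by locating the left and right
crossings of the detection threshold (a fraction of K, default 2 %) with
linear interpolation between grid nodes and averaging the two distances
from the scratch centre; a profile everywhere above the threshold is a
closed scratch (half-width 0), and one everywhere below it is flagged as
degenerate. With two unequal fronts the mean is reported, matching the
half-width's definition as half the vacant width.

## Leading-edge image analysis

The pipeline mirrors the established Matlab workflow: Canny edge map →
dilation with a disk (radius 15 px) → the vacant mask is the complement,
with vacant components under 10,000 px removed (monolayer gaps, not the
scratch) → erosion of the cell mask with the same disk (reversing the
dilation) → 3 × 3 median smoothing → the vacant area
$A(t)$ = vacant pixels × pixel area, and $L_E(t) = A(t) / (2 L_y)$, the
half-width of the equivalent rectangular scratch. Defining $L_E$ through
the *vacant* area is the only convention consistent with the step initial
condition and with closure driving $L_E \to 0$. The relative wound
density, provided for comparison with standard instrument output, is
$1 - A(t)/A(0)$ clipped to [0, 1].

Canny is implemented in full (Gaussian smoothing at σ = √2, Sobel
gradients, non-maximum suppression, hysteresis) because no installed R
package provides it; morphology, labelling and contours use EBImage.
Automatic thresholds take the high threshold from Otsu's method on the
gradient-magnitude histogram with low = 0.4 × high — a deterministic,
logged stand-in for Matlab's unpublished automatic rule, judged by area
accuracy rather than mask identity. Binary median filtering is an exact
majority vote via integral images (EBImage's percentile filter is
needlessly slow on 0/1 masks). Connected components use 8-connectivity
(EBImage's 4-connected labels plus diagonal unions). The pixel size is a
required configuration value (1.37 µm/px for the synthetic instrument,
giving 1438 × 1044 px frames); pixel x-coordinates are
(column + 0.5) × pixel size from the top-left pixel centre.

## Sequential estimation

The estimator is deliberately sequential — one parameter, one data
modality at a time — so each estimate retains a direct mechanistic
reading; no simultaneous multivariate fit is attempted.

* **K**: mean subregion count at the final (confluent) time divided by
  A_SR = 3.789 × 10⁴ µm²; spread is the sample standard deviation (n − 1)
  on the same scale. A single count yields sd 0 with a warning; all-zero
  counts warn of a degenerate carrying capacity.
* **C₀**: the same at t = 0.
* **λ**: per experimental replicate, subregion densities (averaged over
  subregions at each time, default times 0, 8, 16, 24, 46 h) are fitted to
  the closed-form logistic with K and C₀ fixed, minimising the unweighted
  sum of squares; the condition estimate is the replicate mean ± sd.
* **D**: per replicate, the observed half-width series is fitted to the
  numerical solution's half-width (initial half-width taken from that
  replicate's first frame), again unweighted least squares; replicate
  estimates are averaged. The detection threshold is rerun at 1 % and 5 %
  of K to bracket D: a lower threshold places the model edge deeper into
  the scratch, implying less spreading and a smaller D, so the bracket is
  ordered D(1 %) ≤ D(2 %) ≤ D(5 %) — a monotonicity the tests assert.

Both fits are one-dimensional bounded least-squares problems and are
solved with Brent's method (`stats::optimize`), the natural R counterpart
of a bounded nonlinear least-squares routine for a scalar parameter:
λ ∈ [10⁻⁴, 1] /h, and D ∈ [1, 10⁴] µm²/h searched on a log scale (the
literature spans 10¹–10³ µm²/h). Estimates landing at a bound raise a
warning with the fitted value. Each stage failure aborts with a
stage-labelled error so a pipeline run reports *where* it broke.

## The synthetic-assay generator

The generator is the package's test bed: it emulates the imaging protocol
(2-h frames, 46 h, three replicates, three counting subregions of
A_SR behind the scratch) with known ground truth.

* **Truth**: the forward PDE solution at the frame times; the clean
  half-width series is the 2 %-of-K contour of those profiles.
* **Counts**: N ~ Poisson(C·A_SR) per subregion and time (the natural
  counting model), or deterministic round-half-up counts when noise is
  disabled. At the default C₀ the initial subregion counts are ~26 cells.
* **Half-width noise**: Gaussian with sd 10 µm (the scale of
  edge-detection scatter), clipped at 0.
* **Images**: phase-contrast-like frames — bright textured disks on a
  darker background, Gaussian pixel noise (sd 0.03) — rendered only for
  the image-pipeline tests (tabular outputs suffice for the estimators,
  so rendering is opt-in). Cell radius follows contact-inhibited
  spreading: the confluent radius is the area-filling value
  $1/\sqrt{\pi K}$ (≈ 12 px), and sparser cells spread linearly up to
  twice that. Centres are laid down by stratified inverse-CDF sampling in
  x with a jittered low-discrepancy spread in y: local mean counts match
  C(x)·area exactly (verified by a χ² window test), while the pattern has
  the sub-Poisson regularity of a real settled monolayer — a pure Poisson
  draw produces multi-hundred-µm² voids at the wound margin that no
  contact-inhibited sheet shows, and which the edge pipeline mistakes for
  vacancy.

Every stochastic artefact is reproducible from (configuration, seed);
sub-seeds for counts, noise and frames are derived deterministically.

### What the virtual microscope does and does not capture

On sharp wound margins (step-like profiles, half-widths 100–600 µm) the
rendered frames round-trip through the edge pipeline to within 15 µm of
the true half-width. On mid-assay *diffuse* fronts the detected edge of
the rendered stacks corresponds to a density of about **13 % of K** —
higher than the ~2 % documented for real phase-contrast imaging — because
rendered pioneer cells are compact disks without the long protrusions
that real detection picks up. We quantified this by re-running the
standard threshold-correspondence calibration on rendered stacks (the
same experiment that pins real imaging near 2 %) and froze the measured
fraction as the virtual instrument's calibration; the diffuse-front
round-trip test compares detection against that contour. Consequently,
passing image tests demonstrate the pipeline's geometric fidelity, not
that the renderer reproduces the optical tail behaviour of real cells;
image-derived series from the renderer should be fitted at the virtual
instrument's calibrated fraction, while real data use 2 %.

## The finite-horizon confluence bias

The K stage *assumes* the final-time counts are taken at confluence. With
the control parameters this premise is only approximately true at 46 h:
the logistic reaches $C(46)/K = C_0/\{C_0 + e^{-\lambda\cdot 46}(K -
C_0)\} \approx 0.94$, so on data generated by the model itself the
estimator returns ≈ 0.94·K (−6 %), the λ fit with that depressed ceiling
overshoots by ≈ +27 % (noise-free), and D compensates low by ≈ −12 %.
This is a property of the sequential design at a finite horizon, not an
implementation defect: the identical pipeline run on an assay extended to
a genuinely confluent horizon (duration 92 h, λT ≈ 4.7) recovers K, λ and
D to 0.4 %, 3 % and 0.8 % respectively — residuals explained by integer
count rounding and the grid. Both recovery figures are computed by the
test suite and by `scripts/acceptance.R` (the `recovered_*` versus
`selfcheck_*` entries). Practically: if λT at the final counting time is
much below ~4, K estimates should be treated as lower bounds and λ
estimates as upper bounds.

## Problem sizes and runtime choices

The default solve uses 1971 spatial nodes × 460 time steps (well under a
second per solve in compiled code). Recovery studies use 20 seeded assays
with 3 replicates each; the front-speed diagnostic uses an 8000-µm domain
integrated to 400 h, where the late-time half-width slope lies within 5 %
of the classical pulled-front speed $2\sqrt{D\lambda}$ (the remaining
deficit is the known slow logarithmic approach plus a small implicit-step
correction). Unit tests shrink the geometry (400 × 300 µm, 2 µm/px) and
scale the morphology parameters by physical area; the strip-accuracy and
ring-bound properties are asserted at full scale, where the pipeline's
defaults are meaningful.

## Known limitations

* Chemotaxis, density- or space-dependent coefficients, and single-cell
  behaviour (division events, tracks, morphology) are out of scope; the
  model is the constant-coefficient FKPP equation.
* The estimator fits λ per replicate on subregion-averaged densities;
  alternative poolings (per-subregion fits) would give slightly different
  spreads.
* The reported D interval reflects the detection-threshold bracket
  (1–5 % of K), not a sampling confidence interval; replicate sd is
  exposed separately.
* The Canny automatic-threshold rule is a documented Otsu-based choice,
  not a bit-for-bit reproduction of Matlab's; accuracy is asserted on
  areas, not masks.
* The renderer's noise and texture are stylised; statistical fidelity is
  asserted only at the level the pipeline consumes (edges and counts).
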