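# scratchfk

Mechanistic analysis of scratch (wound-healing) assay image data with the
Fisher–Kolmogorov model.

Standard readouts of live-imaging scratch assays — above all the *relative
wound density*, the fraction of the initially scratched area re-occupied by
cells — measure how fast a wound closes but say nothing about *why*: closure
is driven jointly by cell migration and cell proliferation, and a treatment
may act on either. `scratchfk` separates the two by calibrating the assay to
a reaction–diffusion model, yielding three interpretable cell-level
parameters instead of one closure curve. It is aimed at quantitative cell
biologists and modellers working with IncuCyte-style time-lapse scratch
assays (e.g. PC-3 prostate-cancer cells under EGF treatment).

## The model and the estimator

The y-averaged cell density `C(x, t)` (cells/µm²) across the scratch obeys
the one-dimensional Fisher–Kolmogorov (FKPP) equation

    ∂C/∂t = D ∂²C/∂x² + λ C (1 − C/K)

on `0 ≤ x ≤ Lx` with zero-flux boundaries and a step initial condition
(density `C₀` outside the scratch, 0 inside), where

* `D` — cell diffusivity (µm²/h), undirected motility;
* `λ` — low-density proliferation rate (/h), doubling time `ln 2 / λ`;
* `K` — carrying-capacity density (cells/µm²) at confluence.

The solver uses central differences in space, backward Euler in time,
Picard (fixed-point) linearisation of the logistic term, and the Thomas
algorithm for the resulting tridiagonal systems (δx = 1 µm, δt = 0.1 h,
Picard tolerance 10⁻⁶ by default).

The three parameters are estimated **sequentially**, each stage holding the
previous ones fixed:

1. **K** = ⟨N⟩/A_SR from cell counts in subregions (area
   A_SR = 3.789 × 10⁴ µm²) well behind the scratch at the final,
   confluent time point;
2. **λ** by bounded least squares matching the closed-form logistic
   solution to the subregion densities over time (`C₀` taken from the
   first frame);
3. **D** by bounded least squares matching the observed scratch half-width
   `L_E(t)` — extracted from the images by a Canny + morphology pipeline
   and the area relation `L_E = A_vacant/(2 Ly)` — to the half-width of
   the numerical PDE solution, with the detected edge interpreted as the
   2 %-of-K density contour (re-run at 1 % and 5 % to bracket `D`).

A fully seeded synthetic-assay generator (forward PDE simulation, virtual
phase-contrast-like microscopy, Poisson subregion counts, noisy half-width
series) makes the whole pipeline testable by parameter recovery without any
external data.

## Worked example

Generate a synthetic control assay and run the full sequential estimator on
its noisy outputs:

```r
library(scratchfk)

cfg   <- assay_config(seed = 42)        # control parameters, 46 h protocol
assay <- generate_assay(cfg)
assay
#> <synthetic_assay> 3 replicate(s), 24 frame time(s), seed 42
#>   truth: D = 132, lambda = 0.0507, K = 0.00113, C0 = 0.000684, LE0 = 300 um

est <- sequential_estimate(assay$counts, assay$le_noisy,
                           a_sr = cfg$a_sr, geom = cfg$geom,
                           config = cfg$solver, condition = "control")
est
#> <condition_summary> control
#>   K      = 0.001106 +/- 9.089e-05 cells/um^2
#>   C0     = 0.0007097 +/- 6.913e-05 cells/um^2
#>   lambda = 0.05689 +/- 0.01168 /h (doubling time 12.2 h)
#>   D      = 117 um^2/h (threshold interval 96.56-160.6)
```

The recovered triple sits close to the generating truth
(D = 132 µm²/h, λ = 0.0507 /h, K = 1.13 × 10⁻³ cells/µm²); the `K` and
`λ` estimates carry the finite-horizon confluence bias of the sequential
design, quantified in the methods vignette. Results are tidyverse-friendly:

```r
tidy(est)
#> # A tibble: 5 × 6
#>   condition term     estimate spread_low spread_high unit
#>   <chr>     <chr>       <dbl>      <dbl>       <dbl> <chr>
#> 1 control   K        0.00111    0.00101     0.00120  cells/um^2
#> 2 control   C0       0.000710   0.000641    0.000779 cells/um^2
#> 3 control   lambda   0.0569     0.0452      0.0686   /h
#> 4 control   D      117.        96.6       161.       um^2/h
#> 5 control   t_d     12.2       NA          NA        h
```

Comparing published per-condition estimates against the control quantifies
which mechanisms a treatment touches — for the bundled PC-3/EGF reference
table, carrying capacity barely moves while motility nearly doubles:

```r
condition_variability(pc3_egf_estimates())
#> # A tibble: 3 × 3
#>   parameter max_rel_dev_pct worst_condition
#>   <chr>               <dbl> <chr>
#> 1 K                    7.96 EGF-25
#> 2 lambda              36.9  EGF-50
#> 3 D                   81.8  EGF-125
```

A thin command-line interface wraps the same functions
(`inst/cli/scratchfk`): `simulate`, `detect`, `fit-growth`,
`fit-diffusivity`, `estimate` and `summarize`, each writing its resolved
configuration beside its outputs for exact reruns.

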