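---
title: "The flip-flop inflow method: signal model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flip-flop inflow method: signal model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipflow)
```

## The measurement

Slow laminar flow — sap moving through xylem vessels at tens of
micrometers to a few millimeters per second — modulates the multi-slice
spin-echo signal through the *inflow effect*: spins that enter an
excited slice between repetitions arrive fully magnetized, while spins
that stayed put have only recovered `1 - exp(-TR/T1)` of their
equilibrium magnetization. Running the same acquisition twice with
opposite slice-selection order (the **flip** and **flop** orderings)
makes a shared slice alternately inflow- and outflow-sensitive;
subtracting the two magnitude images cancels every static contribution
and leaves a signed, velocity-weighted map.

### Voxel signal model

A voxel holds a moving pool (`M0m`, `T1m`, `T2m`) and a static pool
(`M0s`, `T1s`, `T2s`). Over one repetition period at plug speed `v`,
the slice of thickness `Thk` gains a fully magnetized slab
`dz_T1 = v (TR - TE)`, an undetected slab `dz_T2 = v TE` (spins that
arrive between excitation and echo missed the 90° pulse), and keeps a
resident fraction `beta = (Thk - dz_T1 - dz_T2)/Thk` at
saturation-recovery magnetization (`spin_fractions()`). The
inflow-sensitive (flip) signal is

```
S_flip = Afov kc [ M0m e^{-TE/T2m} ( Thk (1 - E1) + v (TR E1 - TE) )
                 + M0s e^{-TE/T2s} Thk (1 - E1s) ],   E1 = e^{-TR/T1m},
```

while the flop ordering excites the upstream neighbour slice a moment
earlier, so inflow arrives freshly saturated and only a thin slab
`v NS TE` is lost from the moving-pool term. Their difference,

```
S_flip-flop = ± Afov kc M0m e^{-TE/T2m} v [ (TR - NS TE) E1 + (NS - 1) TE ],
```

is odd in the signed velocity, exactly linear below saturation, and
contains no static-pool parameter. Two equivalent-looking forms of the
flip signal circulate (one grouped via the generic inflow
decomposition, one via the ordering-specific derivation); direct
expansion shows they are *algebraically identical*, and both are kept
as separate functions (`inflow_signal()`, `flip_signal()`) with their
equality asserted in the test suite. A distributed-TR variant (slices
spread at `TR/NS`) is provided alongside
(`flipflop_distributed()`).

All closed forms are checked against an independent discrete
spin-transport simulation (`transport_oracle()`): parcels advected
along the slice axis, slice-selective saturation events, exponential
T1 recovery, `e^{-TE/T2}` readout. On the slow-flow grid
(`v TR / Thk` up to 0.8) oracle and closed forms agree within 1% at
10^4 parcels; beyond `v = Thk/TR` the oracle shows the saturation
plateau that the closed forms clamp to.

### Sign and units conventions

Positive velocity means flow in the direction that makes the measured
slice inflow-sensitive in the flip ordering, so positive flow appears
hyper-intense in the flip-minus-flop image. Velocities are mm/s, times
s, lengths mm; signal is in arbitrary units with `kc * Afov` a single
overall scale. When `v (TR - TE) + v TE > Thk`, the most recent inflow
(`dz_T2`) takes precedence and `dz_T1` fills the remainder — the
last-in spins physically occupy the entry side of the slice.

## Absolute calibration via the truncated Poiseuille profile

A Poiseuille profile `v(r) = vmax (1 - (r/R)^2)` has disc mean
`vmax/2`. The inflow measurement, however, cannot register speeds above
the *saturation velocity* `vsat = Thk/TR` — inflow replacement is
already complete — so the apparent profile is clipped at `vsat` inside
the radius `rsat = R sqrt(1 - vsat/vmax)`. The apparent disc mean
becomes the piecewise function

```
v_app(vmax, Thk, TR) = vmax/2                          if TR <= Thk/vmax
                     = vsat (1 - vsat / (2 vmax))      otherwise,
```

continuous at the boundary (the Heaviside boundary point is assigned to
the untruncated branch; both branches coincide there, so the choice is
immaterial). Closed forms are verified against adaptive quadrature of
`min(v(r), vsat)` at relative tolerance 1e-10 — integrands are smooth
polynomials, so the cost is negligible.

This TR-dependence is the calibration lever: the mean ROI subtraction
signal over a TR series follows

```
S(TR) = scale * TR * k(TR) * v_app(vmax, Thk, TR),
```

with `k(TR)` the difference-signal kernel and `scale` a nuisance
amplitude. `fit_vmax()` profiles `scale` out linearly and locates
`vmax` by a 200-point log-spaced grid search over
`[1e-3, 50] * Thk/max(TR)` followed by bounded 1-D refinement. The
reported `recommended_TR_bound = Thk/vmax_hat` tells the user how fast
they may run subsequent monitoring acquisitions while staying below
truncation.

### Kernel choice

The kernel defaults to the exact concentrated-TR difference law
`k(TR) = [(TR - NS TE) E1 + (NS - 1) TE] / TR` rather than its
`NS TE << TR` simplification `E1`. The reason is quantitative: a
calibration series reaching down to `TR = 0.1` s with `TE = 15` ms and
two slices has `NS TE / TR = 0.3` there, where the simplification is
about 14% off; across the bench series this inflates the recovered
`vmax` bias from under 1% to about 4% in the noiseless limit. The
simplified kernel (`variant = "case1_simplified"`) and the
distributed-TR kernel (`"case2"`) remain selectable, and the truncated
apparent-mean substitution is identical in all variants.

### T1m is an input, not a parameter

The moving-pool `T1m` multiplies the kernel in a way that is nearly
collinear with (`scale`, `vmax`) over realistic TR ranges; co-estimating
it creates a three-parameter degeneracy. It is therefore measured
separately — `t1_fit()` fits the saturation-recovery law
`A (1 - e^{-TR/T1})` to static-region means of the same liquid — and
passed to `fit_vmax()` as a constant, mirroring how the measurement is
done in practice.

### Identifiability and the choice of the TR series

Below truncation the model is `S(TR) = scale * TR * k(TR) * vmax/2`:
`scale` and `vmax` enter only through their product, so a series that
never crosses `TR = Thk/vmax` cannot identify `vmax` at all — the
profiled least-squares objective is exactly flat. `fit_vmax()` detects
this (fitted `vmax` at or below `Thk/max(TR)`, or a flat objective) and
attaches an identifiability warning rather than reporting a spurious
number. Consequently the default bench calibration series,
`bench_tr_series()`, spans 0.1 to 5.0 s: at the reference pump setting
(peak 0.2 mm/s, `Thk = 0.5` mm) truncation begins at `TR = 2.5` s, and
the four longest TRs (2.6–5.0 s, up to half the disc clipped) carry the
calibration information. The short end of the series anchors the
untruncated amplitude. As a design rule: the series must bracket
`Thk/vmax`, which the recommended bound reported by a pilot fit makes
easy to check.

## The synthetic bench

`bench_preset()` reproduces the validation-bench geometry used to
demonstrate the method: a 3 mm inner-diameter tube loop carrying equal
and opposite Poiseuille flows (so the two tubes appear as hyper- and
hypo-intense discs), pure water (`T1m = 2.46` s) in a weak short-T2
static surrounding, imaged at 20 mm FOV, 128 × 128, `TE = 15` ms, two
slices, two averages. The water `T2m` is set to 2 s (bulk water at
high field, slightly shortened by inhomogeneity); with `TE = 15` ms
the `e^{-TE/T2m}` factor is within 1% of unity, so this choice is
inconsequential. Rendering rasterizes each tube with 4 × 4 sub-pixel
supersampling (area-weighted occupancy controls partial-volume bias at
the edge), evaluates the closed-form flip/flop signals per pixel, and
adds zero-mean Gaussian noise of `noise_sigma/sqrt(AVG)` per image.

The default `noise_sigma` is calibrated so that a 10 µm/s flow is a
two-sigma effect per difference-image pixel in a single average — the
slowest flow the bench is expected to resolve marginally. It remains a
free parameter.

What the generator deliberately does **not** emulate: Rician magnitude
statistics (the additive-Gaussian model matches the high-SNR regime the
SNR analysis assumes; at very low SNR the floor of a Rician background
would bias magnitude statistics), imperfect slice excitation profiles
(in practice these reduce signal for thick slices; thin slices, under
1 mm, are recommended), flip/flop mis-registration from asymmetric
gradients, through-plane geometry changes, and intra-voxel
bidirectional flow (which partially self-cancels in the subtraction; a
documented physical limitation of the method, not corrected here).
Passing tests therefore demonstrate correctness of the *method
implementation* under its own model assumptions, not robustness to
every scanner artifact.

## Processing pipeline

`subtract()` forms the signed difference image. `segment_flow()`
estimates the noise level from a flow-free border frame (width 10% of
each dimension), thresholds at 4 sigma (conservative against speckle at
these matrix sizes), labels 8-connected components, and drops regions
under 5 pixels. The ROI statistic is the *mean signed signal* with one
fixed mask applied across the whole TR series: the truncation model
describes the area-averaged apparent velocity, magnitude averaging
would bias toward zero near the null, and a fixed mask turns any
threshold or partial-volume selection effect into a TR-independent
factor absorbed by the fitted amplitude — which is why `vmax_hat` is
insensitive to it (doubling the static background changes the estimate
by well under 1% in the test suite).

`calibrate()` divides the difference image by
`scale_hat * TR * k(TR)` to produce a per-pixel velocity map. Because
`scale_hat` is estimated from an ROI mean diluted by partial-volume
edge pixels, absolute per-pixel velocities of interior pixels are
overestimated by the ROI's occupancy deficit (about 10% at the bench
resolution). The velocity *shape*, relative changes over time, and
`vmax_hat` itself are unaffected.

## Sequence design

At fixed total acquisition time `Tacq = AVG * TR`, the SNR of the
difference signal is proportional to
`v * sqrt(Tacq * TR) * e^{-TR/T1m} * e^{-TE/T2m}`; maximizing over TR
gives `TR = T1m/2` — 1.23 s for water at `T1m = 2.46` s.
`optimal_tr()` returns the closed form alongside a numeric argmax over
`(0, 5 T1m]` and asserts their agreement to 0.1%. TE is held fixed
during the optimization; it enters only through the constant
`e^{-TE/T2m}` factor.

## Numerical choices and problem sizes

* Quadrature: `stats::integrate`, relative tolerance 1e-10.
* Fit: 200-point log-spaced grid + `stats::optimize` refinement,
  tolerance 1e-10 on the bracket.
* Transport oracle: 10^4 parcels, simulated for
  `ceiling(6 T1m / TR)` periods plus full slice transit; comparison
  tolerance 1% (fixed before comparing).
* Degenerate inputs: an all-zero ROI yields `vmax_hat = 0`; an empty
  segmentation is a valid result with a warning; saturated pixels are
  counted and logged, never errors.
* The bundled test and validation workloads use the 128 × 128 bench at
  13 TR values with 20 replicate seeds — sizes chosen so the full
  recovery study reruns in seconds while leaving Monte-Carlo error well
  below the tolerances it is checked against.
* Image I/O: NIfTI-1 float32 with a JSON sidecar that is authoritative
  for timing (NIfTI headers cannot carry TE, slice ordering, or a TR
  table); round-trips are exact at float32 precision and idempotent
  thereafter.

## A worked example

```{r example, eval = FALSE}
ph  <- bench_preset(vmean = 0.1, seed = 1)      # peak 0.2 mm/s
ser <- render_series(ph, bench_tr_series())
fit <- fit_vmax(ser, t1m = 2.46)
fit
#> Truncated-Poiseuille multi-TR fit
#>   vmax_hat: 0.199 mm/s   (mean velocity 0.09948 mm/s)
#>   recommended TR bound (Thk/vmax): 2.513 s
plot(fit)
vel <- calibrate(subtract(ser$pairs[[7]]), fit) # TR = 1.2 s map, mm/s
```

## Known limitations

* Two-slice contract: the flip/flop signal laws are derived and
  oracle-verified for the measured slice of a two-slice stack; for
  `NS > 2` the expressions use the `NS TE` generalization but only the
  two-slice geometry is guaranteed.
* The per-pixel calibration bias from partial-volume amplitude
  dilution, discussed above.
* Additive-Gaussian (not Rician) noise; high-SNR assumption.
* No registration between flip and flop images (assumed co-registered).
* Velocities above `Thk/TR` are reported as clipped, not extrapolated.
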