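---
title: "Ring likelihoods, multiplicative cue integration, and its breakdown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring likelihoods, multiplicative cue integration, and its breakdown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringhoming)
```

## The model

A navigator returns to a remembered "home" location using discrete
landmarks that are identical from every direction: each landmark tells the
navigator only *how far* home is, not in which direction. A single such
landmark therefore constrains home to a circle of radius $r$ (the trained
home--landmark distance). With radial uncertainty $\sigma_c$, the
likelihood of responding at a point at distance $d$ from the landmark is a
ring-shaped ("donut") density whose cross-section is Gaussian:

$$f_{\mathrm{G}}(d) \;=\; \exp\!\left(-\frac{(d - r)^2}{2\sigma_c^2}\right).$$

The two-dimensional map assigns each location the profile value at its
distance to the landmark and is then normalized over the workspace. No
$2\pi d$ area Jacobian is applied: the map is the 1D radial fit "wrapped"
back around the landmark, which keeps the density ridge exactly at $r$.

With $k$ landmarks the per-landmark maps are combined by pointwise
multiplication (the maximum-likelihood combination rule for independent
cues) and the predicted response distribution is the renormalized product.
The global maximum is the maximum-likelihood home estimate; all
multi-landmark predictions are parameter-free given the single-landmark
fit. Two rings intersect in two points (a bimodal prediction); three
equidistant rings intersect in one (unimodal at home).

### Heavy tails and the breakdown of integration

A product of Gaussians is always Gaussian, so the plain model can only
*average* conflicting cues -- it can never ignore one. Following the
standard robust-integration device, the mixture variant places a second,
much broader Gaussian ("pedestal") under the central ridge, centred on the
same radius:

$$f_{\mathrm{M}}(d) \;=\;
  \exp\!\left(-\frac{(d-r)^2}{2\sigma_c^2}\right)
  \;+\; a\,\exp\!\left(-\frac{(d-r)^2}{2\sigma_t^2}\right),$$

with peak-height ratio $a = 0.12$ and $\sigma_t = 10\,\sigma_c$ by
default. Under small conflicts the central ridges overlap and the product
is a weighted compromise; under large conflicts the product becomes
bimodal and the maximum jumps back to the locations supported by the
consistent cues -- the deviant cue is vetoed, though its pedestal still
disambiguates the two remaining intersections (the one on the deviant
landmark's side keeps more density).

## Parameters

| parameter | meaning | default | origin |
|---|---|---|---|
| `ridge_radius` ($r$) | trained home--landmark distance | fitted | 6 (visual geometry) or 2 (auditory) in the standard configurations |
| `sigma_center` ($\sigma_c$) | spread of the central ridge | fitted | data |
| `sigma_tail` ($\sigma_t$) | pedestal spread | $\max(10\,\sigma_c,\ \texttt{tail\_floor})$ | fixed, never fitted |
| `tail_amplitude` ($a$) | pedestal peak height / central peak height | 0.12 | fixed, never fitted |

All lengths are abstract units; meters and virtual meters are treated
identically. Two documented ambiguities in the tail conventions are both
implemented: `tail_mode = "sd"` (default, $\sigma_t = 10\sigma_c$) vs
`"variance"` ($\sigma_t = \sqrt{10}\,\sigma_c$), and `amplitude_mode =
"peak"` (default, $a$ is a peak-height ratio applied before joint
renormalization) vs `"weight"` ($a$ is a 1D mixture weight, converted
internally to the equivalent peak ratio). The predictions of interest --
compromise at small conflict, vetoing at large conflict with retained-side
dominance -- are robust to these choices; the exact breakdown distance is
not (see Limitations). `tail_floor` (default 10 length units in
`ring_fit()`) keeps the pedestal essentially flat across the default
workspace even when the fitted $\sigma_c$ is small.

## Fitting

`ring_fit()` collapses single-landmark endpoints onto the
distance-to-landmark axis (`polar_collapse()`) and estimates $(r,
\sigma_c)$ from the 1D sample. The literal recipe -- sample mean and SD of
the distances, available as `method = "moments"` and as the
`fit_radial_gaussian()` primitive -- is exact for distances drawn from a
1D Gaussian, but has two known biases for endpoints drawn from the 2D
model itself. First, points sampled from the 2D map have radial law
$p(d) \propto d\,f(d)$ (there is more ring at larger $d$), so the moment
estimate of $r$ is biased by about $\sigma_c^2/r$. Second, for the
mixture variant a large share of the endpoint mass sits in the pedestal,
which inflates the naive SD several-fold. The default `method = "ml"`
therefore maximizes the likelihood of the collapsed distances under
$p(d) \propto w(d)\,f(d)$ with the pedestal parameters held fixed at
their declared values -- only $(r, \sigma_c)$ are estimated, so the tails
remain "chosen, then fixed", and multi-landmark predictions remain
parameter-free. The radial weight $w(d)$ is the arc length of the circle
of radius $d$ around the landmark that lies inside the observation window
(the declared workspace if supplied, otherwise the endpoint bounding
box); for an unbounded window $w(d) = d$. This matters for the mixture
variant: the pedestal extends to the workspace edge, where circles are
angularly clipped, and ignoring the clipping biases $\sigma_c$ upward by
tens of percent. The 1D normalizing constant is computed by trapezoidal
quadrature on 1024 radii (720 angles for the window fractions);
optimisation is Nelder-Mead on $(\log r, \log\sigma_c)$ started from the
median and MAD of the distances, and the fitted $\sigma_c$ is floored at
`sigma_floor`.

At the default study conditions ($r = 6$, $\sigma_c = 1$, mixture data,
$n = 1000$) the ML fit recovers both parameters to well within 5% median
error over seeded replicates; the test suite checks exactly this.

## Predictions and their summaries

`predict_configuration()` reports, from the normalized product map:
the MLE (argmax over cells, ties broken by lowest row-major index --
deterministic and documented), local maxima at or above 50% of the peak in
the 8-neighbourhood (plateaus deduplicated to their lowest row-major
cell), the implied modality, the expected distance to home ("accuracy":
smaller is better), the distribution mean and covariance, the trace of
the covariance ("total variance"), and the 1-SD and 95% covariance-ellipse
areas ($\pi\sigma_{maj}\sigma_{min}$ and
$\pi\,\chi^2_{2,0.95}\sqrt{\det\Sigma}$). The same summaries are computed
for data by `empirical_accuracy()` / `empirical_precision()`, so model
and data columns are directly comparable. `relocation_sweep()` applies
this across conflict sizes for both variants.

Numerical choices: the default grid is a square centred on home with
half-width $r + \max(6\sigma_c, 10)$ and cell size $\sigma_c/5$ (at least
five cells across the ridge, so the discrete argmax is stable; 161 x 161
cells at the defaults). An odd cell count keeps the centre exactly on a
cell, which makes mirror and rotation symmetries exact at the discrete
level. Rings built directly with `ring_density()` must fully contain the
ridge ($r + 4\sigma_c$ around the landmark) or fail with the required
extent; inside predictions the grid is treated as the declared workspace
and broad pedestals and near-boundary relocated landmarks are truncated
at its edge (`clip = TRUE`). Degenerate inputs fail loudly: empty
endpoint sets, fewer than 3 distances, zero radial spread, mismatched
grids, and an all-zero product ("total conflict") are errors, not silent
results.

## The synthetic-data generator

No behavioural data ship with the package; `generate_experiment1()` and
`generate_experiment2()` produce seeded ideal-observer data with the
statistical structure the analysis assumes. Each participant draws an
individual $\sigma_c$ from a lognormal population distribution (base 1.0
length units, dispersion 0.2 -- a free emulation choice recorded in the
metadata, since only between-participant slope ranges are known) and that
participant's endpoints are sampled from the model's own predicted
density per condition: 1/2/3 landmarks at radius 6 (visual geometry; 2
for auditory) for the first design, and the five relocations 0--6 in
steps of 1.5 of one landmark (orthogonally away from the other two) for
the second. Sampling draws grid cells by mass and jitters uniformly
within the cell. Per-participant RNG streams are derived from the master
seed, so any single participant regenerates bit-for-bit.

What the generator deliberately does not emulate: trajectories, release
points, detours and teleportation (they only serve to remove path
integration, which the model already assumes away), training dynamics,
auditory source segmentation (an optional pair-confusion mode scatters a
fraction of 3-landmark trials between landmark pairs, off by default),
and any response bias not captured by the ring model. Passing tests
therefore show that the pipeline is self-consistent and correctly
calibrated -- not that real participants obey the model.

## Design decisions worth knowing

* **Remembered radii.** Relocated rings are centred on the test-time
  landmark but keep the trained ridge radius: the home--landmark distance
  was learned before the relocation.
* **Model-vs-data calibration.** The paired model-vs-data t-test is
  checked as a calibration property: data generated from known
  parameters are compared against the predictions of that same generating
  model, aggregated over the participant population (equal-weight mixture
  of per-participant densities). Under this self-consistent design the
  test is non-significant in about 95% of replicates per measure, as a
  correctly sized test should be. Comparing against a single pooled fit
  instead mixes pooling error into the test and rejects noticeably more
  often -- that variant is available through `run_experiment()`, which
  follows the fit-on-one-landmark-then-predict pipeline.
* **Accuracy conventions.** Both the expected distance to home under the
  predicted distribution and the distance of the MLE itself are reported;
  the former is the quantity compared against the empirical mean
  distance.
* **Ellipse convention.** The 95% ellipse is the covariance ellipse at
  the $\chi^2_2$ 0.95 quantile (standard, smooth, exact for Gaussian
  clouds), not a data hull.

## Limitations

* **The pedestal carries real mass.** A pedestal with 12% peak amplitude
  and $10\times$ spread holds more integrated mass than the central ridge
  it supports (in 1D, $0.12 \times 10 = 1.2\times$). Full-distribution
  summaries of the mixture variant -- expected accuracy, total variance --
  are therefore substantially larger than those of the plain Gaussian
  variant even without any cue conflict, especially for the 3-landmark
  product where the small central value is easily inflated by residual
  pedestal and mirror-intersection mass. The two variants agree in their
  *maxima* and modal structure without conflict, but not to within a few
  percent in moment summaries; any pedestal small enough to change that
  would no longer produce the breakdown. Users comparing variants should
  compare MLEs and modal structure, or restrict moments to a region of
  interest.
* **The pedestal is not scale-free.** Its mass grows with workspace area;
  at the auditory radius (2) with the default workspace the pedestal
  dominates the ring. Fit quality is unaffected (the fit is 1D), but
  mixture-variant *sampling* at small radii is pedestal-heavy.
* **The breakdown distance depends on $\sigma_c$.** With the default
  generator spread ($\sigma_c = 1$) the sweep jumps between relocations 3
  and 4.5; a rough energy argument puts the critical conflict near
  $\sigma_c\sqrt{6\ln(1/a)} \approx 3.6\,\sigma_c$ for this geometry, so
  reported breakdown points from other spreads differ accordingly. The
  package reports the breakdown as a function of the fitted spread rather
  than as a fixed distance.
* **Discretization.** All summaries are grid sums; with the default cell
  size ($\sigma_c/5$) the expected-accuracy error against dense polar
  quadrature is below 1%, and mode locations are only resolved to one
  cell.

## Problem sizes

The shipped tests and the acceptance script use the study-scale designs
throughout: 10 participants times 40 trials times 3 (or 5) conditions,
161 x 161 grids, 1000-endpoint fits over 20 replicates for recovery, and
50 seeded replicates for the calibration rate. A full test run takes well
under a minute on one core.
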