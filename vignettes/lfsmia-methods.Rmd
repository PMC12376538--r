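---
title: "Counting single-molecule binding events: models and methods in lfsmia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting single-molecule binding events: models and methods in lfsmia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lfsmia)
```

## The measurement problem

A label-free single-molecule immunoassay reads out analyte concentration by
counting individual detection-antibody molecules as they bind analyte
captured on a sensor surface, imaged by plasmonic scattering microscopy
(PSM). Each binding appears as a transient diffraction-limited bright spot
on a large static background; the spot's intensity is linear in the
molecular weight of the binder, which is what lets an image-based detector
tell a ~150 kDa antibody from other material arriving at the surface. The
assay signal is the cumulative number of *specific* binding events over
time, and everything downstream — standard curves, limits of detection,
precision — rests on counting those events correctly.

`lfsmia` implements the full computational chain: a synthetic-video
generator grounded in first-order binding kinetics, the differential-image
detection pipeline, mass-calibrated event classification, a Bayesian
Gaussian-process (BGP) smoother of replicate count trajectories, and
assay-level statistics.

## The kinetic forward model

Cumulative binding counts follow the integral of the instantaneous binding
rate,

$$N(T) = \int_0^T k_{on}\,[A]_t\,[P]_t\,dt,$$

with $[A]_t$ the free captured-analyte sites and $[P]_t$ the detection
antibody concentration, held constant by continuous flow. To realize this
as a discrete event process the simulator maps $[A]_t$ onto a finite number
$S$ of surface sites in the field of view, with $[A]_t$ proportional to the
unoccupied fraction. Writing $r = k_{on}[P]$ for the per-site binding rate,
occupancy $B$ and counts $N$ obey

$$\frac{dB}{dt} = r(S - B) - k_{off}B, \qquad \frac{dN}{dt} = r(S - B),$$

which `expected_counts()` evaluates in closed form. Two consequences the
tests exercise: with $k_{off} = 0$ counts saturate at $S$ like
$S(1 - e^{-rT})$, and with $k_{off} > 0$ counts keep growing linearly after
occupancy equilibrates — the reason a real-time counting assay keeps
gaining signal where an endpoint assay has stalled. `sample_events()` draws
the exact event process whose mean is this integral (per-site exponential
waiting times, exponential dwell), so Monte-Carlo means can be checked
against an independent ODE solution.

Default kinetics: $k_{on} = 10^6\ \mathrm{M^{-1}s^{-1}}$ and 10 nM
detection antibody, giving $r = 0.01\ \mathrm{s^{-1}}$ per site — a
realistic antibody association rate at the concentration used for
detection. $k_{off}$ defaults to 0 because the assay counts arrivals, not
residence.

## The imaging forward model

`render_stack()` draws each active event as an isotropic 2D Gaussian
(default $\sigma = 1.5$ px) with amplitude
`intensity_offset + intensity_per_kda * mass`, on a background of 1000
counts with an optional static low-frequency speckle field (default
relative sd 0.2) and optional linear drift (default 0). Noise is Poisson on
the total intensity plus Gaussian read noise (sd 3). With a 10-frame block
average the differential-frame noise sd is about 14 counts, so the default
`intensity_per_kda = 0.47` puts a 150 kDa antibody spot (~70 counts) at
about five times the differential per-pixel noise sd. That signal-to-noise
ratio is the regime all default thresholds were designed for.

What the generator deliberately does not model: interference-contrast sign
structure, blood-cell occlusion or flow dynamics, mechanical drift, and
detector nonlinearity. Passing tests therefore demonstrate the pipeline's
statistical behavior under its own assumptions, not robustness to every
instrument artifact.

## Detection pipeline

The detector follows the classic differential-imaging chain:

1. **Block averaging** (`rolling_average`): consecutive groups of `n` raw
   frames are averaged (default `n = 10`, i.e. 10 ms effective resolution
   at a 1 ms raw interval).
2. **Mean normalization** (`normalize_frames`): each frame is divided by
   its own mean and rescaled by the global mean, cancelling light-source
   fluctuations while preserving absolute intensity units so the mass
   calibration survives.
3. **Differencing** (`differential`): frame $j+1$ minus frame $j$ removes
   all static structure; arrivals are positive blobs, departures negative.
4. **Probability image** (`probability_image`): cross-correlation with a
   zero-sum center–surround (Haar-like) kernel matched to the PSF size.
   The kernel is a +1/area center square of side $\approx 2\sigma_{PSF}$
   inside a −1/area surround; its exact zero sum makes the response to any
   constant frame identically zero. Border pixels where the kernel does
   not fit are excluded.
5. **Candidates** (`find_candidates`): pixels above mean + 3 sd of the
   whole probability image, de-duplicated by non-maximum suppression
   within one kernel radius.
6. **Sub-pixel fits** (`fit_spot`): Levenberg–Marquardt 2D Gaussian fits
   on the differential frame. A fit is accepted when it converged, its
   relative RMS residual is ≤ 0.5, its $\sigma$ lies in [0.5, 2] × the
   nominal PSF $\sigma$, and its center stays in the fit region.
7. **Trace linking** (`assemble_traces`): accepted fits within 2 px across
   ≤ 1 missing frame merge into one trace; the trace's `peak_intensity` is
   the maximum of its temporal amplitude profile.

### The block-phase problem and the amplitude significance gate

An arrival at a random phase $\alpha$ of an averaging block splits its
amplitude $A$ into $\alpha A$ and $(1-\alpha)A$ across two adjacent
differential frames. Per-frame statistics of such split spots overlap
substantially with fits to pure noise at 5× SNR, so per-frame gates alone
either flood the trace list with noise or sacrifice recall. The package
therefore re-measures every candidate trace on the *skip-difference* image
— averaged block after arrival minus averaged block before — where the
full amplitude $A$ appears regardless of phase, using a fixed-shape
weighted least-squares amplitude with a known standard error. Traces whose
amplitude t-statistic falls below `min_significance` (default 7) are
discarded. At the design SNR a real 150 kDa spot scores $t \approx 13$
while selected noise blobs score $\approx 4$, so the gate separates them
cleanly; measured false-trace rates on event-free stacks sit far below the
3σ-derived budget (`false_trace_budget()`). The same skip-difference
amplitude (`refined_intensity`) is the default intensity for mass
estimation, since it is free of the up-to-2× low bias the raw peak suffers
from phase attenuation.

Departures (negative blobs) are detected by running the same machinery on
the negated differential frames; they only terminate traces and set dwell
times, never increment counts. Arrivals during the very first averaged
block precede the first frame pair and are invisible to any differencing
detector; recovery metrics (`match_traces`) therefore restrict the
denominator to the detectable time window.

## Mass calibration and classification

`fit_mass_calibration()` fits the linear intensity–mass response by
weighted least squares from a table of reference proteins (the bundled
example table, built from BSA/IgG/IgA/IgM masses, is synthetic —
constructed from the generator's own linear response, not measured data).
`classify_events()` then applies, in order:

* **repeated-site rule**: single-linkage clusters of trace centers within
  `colocation_radius_px` (default 1 PSF σ); any cluster with more than
  `max_site_visits` (default 1) events over the record is flagged
  `repeated_site` — binding at the same spot multiple times marks a sticky
  surface site, whatever its mass;
* **mass window**: events whose estimated mass falls outside
  `mass_window_kda` are `mass_out_of_window`. The default window for a
  150 kDa antibody spans roughly ±3 propagated mass sd
  (`default_mass_window()`);
* **duration gates**: dwell below `min_duration_s` (default two averaged
  frame intervals — a real binding must outlive the differential
  transient) or above `max_duration_s` (default ∞, both gates provided).

Every event receives exactly one label and reason code, and
`build_count_series()` accumulates the specific arrivals into the
cumulative count series that is the assay's raw signal. Light contaminants
(≲ 50 kDa) mostly fall below the detection threshold altogether; heavy
ones (≳ 300 kDa) are detected and removed by the mass window.

## The Bayesian Gaussian-process model

Replicate count series of one condition are modeled as noisy observations
of a single latent trajectory $f(t)$:

$$y_{rj} = f(t_j) + \varepsilon_{rj}, \qquad
  \varepsilon_{rj} \sim \mathcal N(0, \sigma^2),$$

on a transformed scale — by default the Anscombe square root
$2\sqrt{N + 3/8}$, which stabilizes the variance of Poisson-like counts.
$f$ has a GP prior with squared-exponential kernel around a straight-line
mean fit to the pooled data; the line's own uncertainty is carried by a
weakly-informative linear basis-function term added to the kernel, so the
posterior band is calibrated rather than anchored to a plug-in trend.
Hyperparameters (kernel amplitude, length-scale, replicate noise sd) have
log-normal / half-normal hyperpriors centered on data-driven scales
(residual sd; a quarter of the time span).

Inference is `map_plus_laplace` by default: the hyperparameter posterior
mode is found by optimizing the log marginal posterior, a Laplace
(Gaussian) approximation around it supplies 40 hyperparameter draws, and
the posterior of $f$ is the mixture of the conditional GP posteriors over
those draws, back-transformed to count units by the exact moments of the
inverse square transform. A random-walk Metropolis `mcmc` mode (split-chain
R-hat and a crude effective sample size always reported) is available when
a full posterior is wanted; both modes are seed-deterministic. This
hierarchy — shared latent trajectory, replicate-level noise, posterior
mean ± sd — is the package's own concrete choice for the BGP smoother;
alternatives (e.g. fitting counts untransformed) are one configuration
switch away.

Cumulative counts are monotone but a generic GP is not; an isotonic
projection of the posterior mean is available (`monotone_projection`) and
off by default, since projecting the mean without adjusting the band would
misstate the uncertainty.

Two properties matter downstream. First, the 95% posterior band for $f$
has empirical coverage close to nominal in simulation. Second, the
endpoint CV from the posterior (`endpoint_estimate`) is substantially
smaller than the CV of the plain 3-replicate endpoint sd
(`naive_estimate`), because the GP pools the whole trajectory across
replicates — digital counting assays are otherwise stuck with the
$1/\sqrt{N}$ shot-noise floor at the endpoint. The package asserts the
direction and magnitude of this gain on simulated data (median ratio ≥ 2,
model better in ≥ 90% of runs), not any specific factor measured on
instrument data.

## Assay quantification

`fit_standard_curve()` fits endpoint estimates against concentration,
weighted by 1/sd². The default is a log-log line (these assays plot as
straight lines on log-log axes over many decades); a four-parameter
logistic is available for saturating ranges. For the log-log model an
optional `baseline` (the blank-condition estimate) is subtracted before
fitting and restored by the forward map — at desk scale the lowest
concentrations sit below the blank level, and fitting gross counts there
would flatten the line and bias inverse prediction.

`compute_lod()` implements the blank-plus-three-sd rule: the threshold
count is the blank posterior mean plus three blank posterior sds, and the
LOD concentration is that threshold through the inverse curve.
`dynamic_range()` is the log10 ratio of the upper quantification limit to
the LOD; `cv()` and `cv_improvement()` are the precision metrics; and
`pearson()` gives the correlation and regression slope used to compare
against a reference assay.

Concentration units are deliberately abstract ("units" of the titration);
the package never converts between mass and molar units implicitly.

## Numerical choices and degenerate inputs

* GP kernels get a diagonal jitter scaled to the kernel's largest diagonal
  entry, so exactly-noiseless replicates (zero residual variance) still
  factor; hyperparameter draws whose kernel is numerically singular are
  skipped, with the MAP draw always retained.
* The BGP fitting grid is the union of replicate time grids, thinned
  evenly beyond 200 points.
* Flat probability images (sd = 0) and frames with non-positive means are
  errors, not silent passes; non-convergent spot fits are rejected fits
  with a reason code, not exceptions.
* All randomness flows through explicit seeds (`withr::with_seed`), so the
  global RNG state is never touched; identical config + seed reproduces
  every pipeline output byte for byte.
* Coordinates are 0-based (row, col) with the pixel-center convention;
  frames are indexed from 0 in all user-facing tables; times are seconds
  from the start of the record.

## Problem sizes used by the tests

The test suite and the acceptance script run at desk scale, chosen so the
statistical claims are testable on one CPU: oracle checks on 64×64×20
stacks; detector recovery on a 256×256×600-frame video with ~100 events at
the design SNR; classification on a 160×160×800 video with mixed
specific / sticky / wrong-mass populations; 200 simulated 3-replicate
experiments for band coverage and for the endpoint precision gain (100
grid points per series, matching the point density of a real-time record);
and a five-log titration (3 replicates × 5 concentrations + blanks) on
96×96×300 videos for the full round trip. Headline numbers from
instrument-scale data (femtogram-per-mL LODs, multi-fold CV improvements
on patient samples) are properties of the physical assay and are not
asserted by these desk-scale simulations.

A desk-scale corner case worth knowing: on small fields of view the
detector can return literally zero false or nonspecific counts for a
blank, in which case the blank-plus-three-sd threshold is numerically zero
and the formal LOD collapses to the floor of the fitted curve. Real
instrument records, with far larger fields and matrix effects, have
nonzero blank signals; the LOD formula is faithful either way, but the
number should be read against the blank's actual count level.

## Known limitations

* The detector assumes a mechanically stable field of view (no drift
  correction or registration).
* One target species per run; overlapping mass distributions are not
  deconvolved.
* The repeated-site rule needs sticky dwell times resolvable at the
  averaged frame interval; sub-frame sticky events are simply never
  detected.
* The GP noise model treats replicate deviations as independent across
  time points, while a counting process has random-walk autocorrelation;
  in simulation the posterior band stays calibrated for the latent
  trajectory, but the noise hyperparameter should not be over-interpreted.
* `k_off > 0` makes specific sites re-bind at a fixed location, which the
  repeated-site rule would then flag; with the default duration gates and
  `k_off = 0` this tension does not arise, but assays for fast-cycling
  binders would need `max_site_visits` raised.
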