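---
title: "Modelling SSB recycling at the replication fork"
author: "SSBrecycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SSB recycling at the replication fork}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SSBrecycle)
```

## The problem

The homotetrameric single-stranded DNA-binding protein (SSB) of
*E. coli* coats the transiently exposed lagging-strand ssDNA at the
replication fork. Two routes can supply SSB to each new Okazaki-fragment
gap: *internal transfer*, in which a tetramer displaced by the
lagging-strand polymerase rebinds freshly exposed ssDNA behind the
helicase without ever leaving the fork, and *external exchange*, in which
fork-bound SSB is replaced by tetramers from solution at a
concentration-dependent rate. The balance between the two routes is
measured by single-molecule FRAP on rolling-circle replication assays and
by pinhole FRAP in live cells. This package implements both the stochastic
generator for such data and the full inference chain, so that every
published quantity can be re-derived as a parameter-recovery experiment:
inject a known value into the generator, run the pipeline, and check that
the estimate comes back.

## The kinetic model

A replisome synthesizes DNA at a per-replisome rate $v \sim
\mathcal N(v_\mu, v_\sigma)$ (defaults 750 and 70 bp/s; the wild-type
calibration experiment uses 626 ± 73 bp/s). Okazaki-fragment lengths are
i.i.d. exponential with a concentration-dependent mean taken from a
four-point table (1.4, 1.5, 2.0 and 2.8 knt at 2, 10, 20 and 100 nM SSB,
interpolated log-linearly in concentration). Each fragment cycle exposes
the fragment's ssDNA, which is tiled by tetramers at 35 nt per tetramer
(only the 35-nt binding mode is modelled; interconversion with the 65-nt
wrapping mode is abstracted away).

Two stochastic channels act on fork-bound tetramers:

* **Solution exchange**: each bound tetramer is replaced from solution as
  a Poisson process with rate
  $k_{ex}(c) = k_{intr} + k_{fac}\,c$. The defaults
  ($k_{intr} = 0.01\,\mathrm{s^{-1}}$,
  $k_{fac} = 0.0033\,\mathrm{nM^{-1}s^{-1}}$) reproduce the fast-exchange
  regime at 100 nM ($\tau = 1/k_{ex} \approx 2.9$ s). A least-squares
  calibration helper (`calibrateExchangeLaw()`) is provided; note that a
  two-constant pseudo-first-order law cannot pass exactly through all
  three published exchange times, so recovery experiments inject the
  target value directly ($k_{intr} = 1/\tau$, $k_{fac} = 0$) rather than
  relying on the default calibration.
* **Displacement**: at the end of every completed fragment the polymerase
  displaces the bound complement; each tetramer transfers internally with
  probability $p_{int} = s/(s + c)$ (competition constant $s = 20$ nM by
  default, the simplest saturable competition) and otherwise leaves to
  solution.

Two modelling choices deserve emphasis:

* **Constant Okazaki-scale occupancy.** The slot count per cycle is set
  by the *mean* fragment length, not each fragment's own draw. If the
  complement tracked each exponential fragment length, the bound
  population would re-equilibrate with solution every cycle (about half
  the complement per cycle), which is incompatible with measured exchange
  times an order of magnitude longer than a fragment time; physically,
  the replication loop smooths per-fragment demand. With constant
  occupancy the post-pulse expected bright fraction is exactly
  $1 - e^{-k_{ex}t}$.
* **FRAP templates run with $p_{int} = 1$.** With the default competition
  constant, displacement losses would add a second solution-influx
  channel of rate $(1 - p_{int})/t_{OF}$ on top of $k_{ex}$, and the
  single fitted exchange time would no longer equal
  $1/(k_{intr} + k_{fac}c)$. Since the chase experiment shows internal
  transfer is highly efficient, the FRAP parameter-recovery templates
  disable displacement loss so that the injected exchange time is the
  exact ground truth of the measured recovery. The general fork model
  (chase, recycling metrics) keeps the competition law.

## Photophysics and imaging

Labelled tetramers carry 1 or 2 dyes (mean 1.5); dyes bleach
independently with lifetime $\tau_b$ under continuous illumination
(default 9.5 s, the value recovered by the chase experiment). Acquisition
may be stroboscopic: with exposure $e$ per frame interval $\Delta$, the
wall-clock bleach rate is $e/(\Delta\,\tau_b)$. The chase/continuous
templates use full duty ($e = \Delta$), so the ensemble fork intensity
decays at $\tau_b$ in wall time. The in-vitro FRAP templates use 12 ms
exposures at 0.5 s intervals (duty 2.4%), a standard sparse-sampling
protocol that keeps the imaging-bleach contribution to the measured
replacement rate below 5% even at the slowest exchange time (20 s);
recovery is measured by the fluorescence returning after a high-power
pulse that instantaneously bleaches every fork-bound dye while flow keeps
the solution pool bright.

A FRAP trace is fitted, after normalizing the pre-pulse steady state to
1 and averaging the first three recovery phases of every replisome with
equal weight per phase, with the combined photobleach-corrected model

$$I(t) = a\,e^{-t/\tau_b} + I_0\,(1 - e^{-t/\tau}),$$

by bounded Levenberg-Marquardt least squares. Initialization: $\tau$ from
the time to half recovery over $\ln 2$, $\tau_b$ from the tail slope, $a$
from $I(0)$, $I_0$ from the plateau; a small multi-start set over
$\tau_b$ guards against the shallow $(a, \tau_b)$ valley when the two
time constants are comparable. Fits with vanishing bleach amplitude are
re-fit without the bleach term and flagged, and fits where $\tau$ and
$\tau_b$ differ by less than 20% are flagged as near-degenerate.
Uncertainties come from the Jacobian, optionally supplemented by a
bootstrap over recovery phases (`bootstrapTau()`).

## The in-vivo variant

Each cell is an ellipse (4.0 × 1.2 µm) with a finite cytosolic pool of
1200 labelled tetramers and 1-4 replisome foci of 30 tetramers each;
the fluorescent-protein fusion contributes one fluorophore per tetramer.
A diffraction-limited pulse (Gaussian, 500 nm FWHM) bleaches dyes with
probability $e^{-r^2/2\sigma^2}$, darkening one focus while the cytosol
keeps over 90% of its fluorescence. Focus occupants exchange with the
cell's own pool, whose bright fraction decays under imaging illumination
(lifetime 20 s at visualization power, frame interval 0.25 s, 25 s
movies — values chosen once as plausible for a YPet fusion under low-power
imaging; none is a published number). The analysis is the two-step
procedure: a single-exponential fit to pooled unpulsed control cells
gives the imaging-bleach lifetime; the averaged pulsed-focus trace is
divided pointwise by that decay and the pure recovery
$I_0(1 - e^{-t/\tau})$ is fitted. For a large pool the measured focus
trace factorizes exactly as
$S f_0 e^{-k_b t}(1 - e^{-k_{ex}t})$, so the two-step correction is
unbiased; the per-frame binomial propagation samples this law without
time-discretization error at the frame times. The pulse is recorded at
the last pre-pulse readout so that phase time zero is consistent with
the first post-pulse frame.

## Rendering and trajectory analysis

Kymographs place the product tip at $vt$ converted through 3.6 bp/nm
(stretched DNA: 500 nm of product corresponds to about 1800 bp) and
160 nm pixels, with a Gaussian PSF ($\sigma$ = 120 nm) and EMCCD-like
noise (Poisson shot plus Gaussian read noise); photon flux is conserved
in noise-free mode. Tracking is per-frame thresholded detection
(median + 5 MAD) with subpixel centroid refinement and nearest-neighbour
linking (maximum step 3 px/frame; the fork is the brightest persistent
spot). Rates come from BIC-penalized piecewise-linear segmentation solved
exactly by dynamic programming (minimum segment 5 s; penalty scale 4
times the difference-based noise variance per breakpoint), pooled into a
Gaussian (moment) fit reported as mean ± SEM. Spots closer than about one
PSF width merge — the documented resolution limit, and the reason
inter-spot Okazaki estimates are truncation-corrected.

## Okazaki-length estimators

The single-molecule estimator pools adjacent SSB inter-spot distances
along product molecules. Distances below 0.5 knt (the diffraction limit
on stretched DNA, conservatively rounded) are unobservable, so the
exponential mean is estimated by the left-truncated MLE
$\hat\mu = \overline{x}_{x \ge c} - c$, with a percentile bootstrap CI;
a histogram-decay fit is available for comparison with curve-fitting
practice but the bin-free MLE is the default. The gel emulation bins
lengths on a log axis (0.05 decades, calibrated by a synthetic ladder),
weights each fragment by its length — staining scales with nucleotides —
and divides the profile by length before computing moments; the raw
profile mean is the length-biased $E[L^2]/E[L]$, twice the mean for
exponentials, which is what the normalization removes.

## Recycling metrics

From an exchange time, fragment length and rate:
$t_{OF} = L/v$, $n_{cycles} = \tau/t_{OF}$, and the per-cycle retained
fraction $e^{-t_{OF}/\tau} = e^{-1/n_{cycles}}$ (an identity asserted in
the tests). The replication rate shows no significant concentration
dependence, so a single shared $v$ is used across concentrations by
default. The 20 nM exchange time was never published: report rows carry
an explicit missing value rather than an interpolation (the fixture
generator, which needs *some* ground truth for that bundle, uses a
log-interpolated value and marks it as unpublished). Tetramer
stoichiometry divides spot intensity by a single-tetramer calibration and
multiplies by the 35 nt footprint.

## Problem sizes and reproducibility

The recovery experiments run at the experimental ensemble sizes: 24/20/18
replisomes for the in-vitro series at 10/2/100 nM, three recovery phases
each; 29 pulsed foci and 40 control cells in vivo; 71 molecules for the
rate distribution; 500 fragments per concentration for the length
estimators; medians over 100 generator seeds for the FRAP recoveries.
Every simulation consumes a single seeded RNG stream; ensembles derive
per-replisome sub-seeds reproducibly from the master seed, and identical
configurations give bitwise-identical ledgers and traces. All stage
boundaries are plain files (CSV/JSON/TIFF with JSON sidecars) written
atomically, so each stage can be fed real data in the same layout. The
canned experiment templates, `runExperiment()` and `makeFixtures()`, are
the package's orchestration surface; being an R library, its command-line
interface is `Rscript` over these functions.

## What the generator does and does not emulate

The generator reproduces the statistical structure the inference relies
on: exponential fragment lengths, Poisson exchange, independent dye
photophysics, Gaussian PSFs, EMCCD-like noise, finite in-vivo pools, and
control cells sharing the field of view. It does not model spatial
diffusion of SSB along ssDNA, the 65-nt wrapping mode, leading-strand or
primase kinetics, polymerase pausing, flow or stage drift, or non-uniform
illumination. Passing recovery tests therefore demonstrates that the
analysis chain is unbiased under the stated stochastic model at realistic
sizes and noise levels — not that these nuisances are absent from real
data.

## Known limitations

* The pseudo-first-order exchange law is an assumption; only the
  concentration trend, not the functional form, is constrained by the
  published exchange times.
* The internal-transfer competition law $s/(s+c)$ is the simplest
  saturable form; $s$ = 20 nM makes transfer and exchange roughly equal
  near in-vivo-equivalent concentrations.
* Exchange is per-tetramer; cooperative whole-cluster exchange is not
  modelled.
* The combined recovery fit is structurally near-degenerate when
  $\tau \approx \tau_b$; such fits are flagged rather than silently
  reported.
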