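---
title: "Models and methods behind psitrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psitrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

psitrap implements the computational workflow used to characterize a
Photosystem I light-harvesting supercomplex (PSI–LHC): global analysis of
time-resolved fluorescence, steady-state band analysis, gradient-fraction
proteomics and pigment stoichiometry. This vignette explains the models,
the defaults and why they were chosen, what the synthetic-data generator
does and does not emulate, and the numerical decisions that matter.

```{r setup}
library(psitrap)
```

## The kinetic model

A streak camera records fluorescence intensity versus time and wavelength.
After excitation through a Gaussian instrument response function (IRF) with
centre $\mu$ and width $\sigma$, the image is modelled as

$$ I(t, \lambda) \;=\; \sum_{n=1}^{N} A_n(\lambda)\,
   \bigl[\, e^{-t/\tau_n} \otimes \mathrm{IRF}(\mu,\sigma) \bigr], $$

a sum of exponential decays with lifetimes $\tau_n$ shared across every
wavelength and every acquisition time range, each weighted by its
decay-associated spectrum (DAS) $A_n(\lambda)$. The convolution has the
closed form implemented by `exp_conv_gauss()`:

$$ \tfrac12\, e^{\sigma^2/2\tau^2 - (t-\mu)/\tau}\,
   \operatorname{erfc}\!\Bigl(\tfrac{\sigma/\tau - (t-\mu)/\sigma}{\sqrt2}\Bigr). $$

Evaluated literally, the two factors overflow and underflow long before
their product does (already at $\sigma/\tau \approx 40$ in double
precision). When the erfc argument $z$ is positive we therefore evaluate
$\tfrac12\,\mathrm{erfcx}(z)\, e^{-(t-\mu)^2/2\sigma^2}$, which is exactly
equal and stable for $\sigma/\tau$ up to at least $10^3$; the erfcx itself
switches to its asymptotic series beyond $z = 20$, where implementations
that form $e^{z^2}$ explicitly break down. The unit tests hold this kernel
to $10^{-6}$ relative agreement with adaptive quadrature of the defining
integral across a grid of $(\tau, \sigma)$.

Sequential ("cascade") compartment models $1 \to 2 \to \dots \to N$ with
unit transfer efficiency are supported through `sequential_profiles()`.
Expanding the cascade populations on the exponential basis gives a
triangular matrix of dimensionless coefficients (`bateman_matrix()`) that
converts exactly between evolution-associated spectra (EAS, per
compartment) and DAS (per exponential); `das_from_eas()` and its inverse
round-trip to $10^{-10}$. Two lifetimes closer than $10^{-9}$ relative make
the cascade solution singular, and the functions refuse them with advice to
perturb rather than returning the numerically meaningless limit.

## Fitting: variable projection

`fit_global()` exploits the model's separable structure. For a candidate
lifetime vector, the amplitudes $A_n(\lambda)$ enter linearly, so they are
solved exactly by least squares at every wavelength; the nonlinear search
runs only over the free lifetimes (variable projection). Lifetimes are
optimized in log space, which enforces positivity without constraints;
initial values default to log-spaced between twice the finest time step and
the longest time window, and seeded random restarts (default 5) guard
against local minima. On small problems the fitted cost matches a
brute-force grid search over lifetimes, which the tests verify.

When several time ranges are fitted jointly the DAS shape is shared and one
free scale factor per image absorbs acquisition-dependent intensity
differences; the first image anchors the scale. The inner problem is then
bilinear in (DAS, scales) and is solved by alternating linear least
squares, which converges in a handful of iterations. Lifetimes known
independently — here the 6 ns free-chlorophyll decay, visible in the
steady-state 77 K emission as a 675–680 nm shoulder — are held fixed via
the `fixed` argument and never moved by the optimizer.

Reporting follows the conventions of the field: the total amplitude $A_n$
of a component is the signed trapezoidal area under its DAS over the
detected wavelength range (`relative_amplitudes()`), relative amplitudes
are shares of the summed signed areas, and the average time to charge
separation

$$ \tau_{\mathrm{avCS}} = \frac{\sum_n \tau_n A_n}{\sum_n A_n} $$

is computed over the *connected* components only
(`average_decay_time()`, `classify_components()`); components slower than
1 ns (default threshold) are classified as disconnected species — detached
antenna and free chlorophyll do not feed the reaction centre and would
otherwise dominate the mean. Applied to the published four-component
tables, this reproduces the reported trapping times (31 ps and 32 ps for
the two preparations) exactly after rounding.

## Model-order selection

`select_n_components()` fits increasing orders and stops when the next
component fails to earn its keep: the relative rms improvement falls below
2% (default), or the larger model contains two lifetimes within 10% of each
other, or it contains a lifetime faster than the instrument response FWHM.
The last rule deserves a comment: with signal-dependent noise, an
unweighted fit can lower the residual noticeably by placing a spurious
ultrafast component in the high-variance peak region, but a component
faster than the temporal resolution is physically unclaimable, so it is
treated as an overfit signature like a duplicate. Ties favour the smaller
order.

The `fix_slowest` argument compares candidate orders with the slowest
lifetime fixed (e.g. at 6 ns), mirroring how such data are analyzed in
practice when one species is known independently. This matters: comparing
fully free models of order 3 and 4, the two slow decays (1.7 ns and 6 ns,
together <20% of the amplitude) can be absorbed into one intermediate
lifetime at a residual cost below realistic noise, whereas with the 6 ns
component pinned the three-component model misfits clearly and the
selection lands on four robustly.

## The synthetic-data generator

The generator is the package's instrument stand-in and defines the
conditions under which the recovery claims are tested.

* **Kinetics** (`kinetic_ground_truth()`): defaults are the published α-DM
  solution — lifetimes 10.5 ps, 45.5 ps, 1.7 ns, 6 ns (fixed) with relative
  amplitudes 33.1/48.9/11/7%.
* **DAS shapes** (`default_das_shapes()`): one Gaussian emission band per
  component, fast components at 687 and 690 nm (bulk PSI–LHC emission),
  slow components blue-shifted to 681 nm (disconnected antenna) and 676 nm
  (free chlorophyll). Giving the two slow species distinct spectra reflects
  that they are distinct emitters; it is also what makes them resolvable at
  all — with identical shapes their sum is fit by a single intermediate
  exponential below any realistic noise floor. Amplitudes are scaled so
  each component's signed DAS area equals its relative amplitude.
* **Acquisition**: three time ranges, 0–155, 0–400 and 0–1500 ps, with
  Gaussian IRFs of FWHM 4.5, 6.5 and 20 ps (the midpoints of the stated
  temporal responses, interpreted as FWHM — the convention instrument
  vendors quote; a σ reading is available by passing widths through
  `fwhm_to_sigma()` yourself). 140 time samples per range and a 640–800 nm
  wavelength axis at 5 nm are the default desk-scale problem sizes.
* **Noise**: Gaussian with standard deviation
  $\mathrm{noise\_scale}\cdot\sqrt{s\,\hat s + f\,\hat s^2}$ where $s$ is
  the local signal, $\hat s$ the image peak and $f = 0.01$ a variance
  floor — photon statistics after camera gain plus readout. The default
  `noise_scale = 0.02` (peak SNR ≈ 50) is a deliberately conservative
  figure for an averaged streak image.
* **Spectra** (`gen_absorption()`, `gen_emission()`): Gaussian band
  mixtures. The 77 K absorption default places four Qy sub-bands at 669,
  679.5, 685 and 697.5 nm with FWHM 9/7/6/8 nm and decreasing amplitudes;
  emission mixes a dominant 722 nm red-form band with a configurable
  free-chlorophyll fraction at 678 nm.
* **Fraction tables** (`gen_fraction_table()`): each protein draws a
  log-normal total abundance and splits it across gradient bands by its
  archetype profile under mean-one multiplicative noise, so raw intensity
  shares equal the profile in expectation. Archetype abundances follow
  thylakoid stoichiometry (bulk LHC 4×, PSII core 2× the PSI-specific
  subunits), which keeps expected per-fraction totals roughly balanced —
  the condition under which sum-based per-fraction normalization is
  unbiased. An optional per-fraction acquisition factor (`run_factor_sd`)
  emulates between-run intensity differences; the normalization cancels it
  exactly, which the tests verify.
* **Pigments** (`gen_pigment_areas()`): the exact inverse of
  `quantify_pigments()`, so generation followed by quantification
  round-trips to $10^{-9}$.

What the generator does *not* emulate: detector saturation,
singlet–singlet annihilation (the measurement conditions were verified
annihilation-free), wavelength-dependent IRF dispersion, vibronic
structure or negative energy-transfer lobes in the DAS, scattering
baselines in spectra, and peptide-level effects in the proteomics
(missing-value mechanisms beyond absence, shared peptides, FDR). Passing
recovery tests therefore demonstrate the correctness and calibration of the
estimators under the stated statistical model, not robustness to every
artifact of real instruments.

## Steady-state spectral analysis

Band detection (`second_derivative_bands()`) computes a Savitzky–Golay
second derivative — default window 11 points, polynomial order 3, suited to
grids of 0.5–1 nm step — and reports local minima deeper than 5% of the
deepest one, with sub-grid positions from a parabola through the three
points around each minimum. Positions are invariant under amplitude
scaling and equivariant under wavelength shifts (tested properties). The
detector requires a uniform grid; resample first if yours is not.

Normalization (`normalize_spectrum()`) offers peak, Qy-region
(620–720 nm) and red-tail conventions; the red-tail mode scales the
trapezoidal integral above a threshold (default 705 nm) to one, the
convention used to compare PSI spectra on a common red-form scale. All
modes are idempotent. `emission_maximum()` uses the same parabolic
refinement and warns when the maximum sits on the boundary of the search
window (monotone spectrum).

## Fractions and pigments

Per-fraction normalization factors are the mean of all fraction intensity
totals divided by each fraction's total. The anchor (mean) is arbitrary —
any constant cancels in the per-protein distributions — and is documented
as such rather than hidden. Proteins absent everywhere are excluded from
distributions and reported via an attribute. Enrichment in a target band
is called at a 75% share by default, the cutoff separating specific
components of the PSI–LHC band from proteins spread across the gradient.
Missing intensities are treated as zeros, the way label-free pipelines
export absence.

Pigment quantification converts peak areas to mol per 100 chlorophylls via
response factors; the vaucheriaxanthin factor is derived from the
violaxanthin one with a +10% correction. The direction of that correction
is a convention (the source protocol does not state the sign); the default
increases the factor, and `vaucheriaxanthin_rf(correction = -0.10)` gives
the opposite reading. Contents reported only as "below x" are carried as
censored values, and `chl_car_ratio()` then returns an interval — the
bounds obtained with the censored pigment at its bound and at zero —
rather than a false point estimate.

## Numerical choices and degenerate inputs

* Lifetimes are the canonical parameterization everywhere; rates appear
  only inside the cascade algebra.
* The inner least-squares solve uses a QR decomposition; a singular design
  (degenerate candidate lifetimes met during optimization) yields an
  infinite cost, steering the optimizer away instead of crashing.
* `fit_global()` is invariant to permutations of the initial lifetime list
  (inits are sorted) and to the order of input images (tested).
* Zero-noise, zero-width-IRF limits are exact: the kernel reduces to a
  sharp-onset exponential, and a single-wavelength single-exponential fit
  agrees with a log-linear regression to $10^{-8}$.
* Problem sizes in the tests and the acceptance script (140 time points,
  5 nm wavelength steps, 10 replicate fits, 50-replicate bias checks on
  two-component reductions) were chosen as the smallest at which the
  statistical claims are meaningful.

## Known limitations

Branched or target kinetic schemes, wavelength-dependent IRF dispersion,
anisotropy, error bars from the nonlinear fit's curvature, Gaussian
deconvolution of absorption spectra, and peptide-to-protein inference are
out of scope. The first kinetic component of real PSI–LHC data retains
energy-transfer character (its DAS lacks part of the expected positive
vibrational band); psitrap classifies it as connected but does not
decompose it into a transfer scheme.
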