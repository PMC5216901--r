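# psitrap

Global kinetic and compositional analysis of Photosystem I supercomplexes
(PSI–LHC), built around the workflow used to characterize the PSI antenna
system of the eustigmatophyte alga *Nannochloropsis gaditana*: time-resolved
fluorescence from a streak camera, steady-state 77 K spectroscopy,
sucrose-gradient proteomics and HPLC pigment analysis.

It is written for photosynthesis researchers who want the computational half
of such a study — the model fitting, band analysis and stoichiometry — as
tested, reusable R functions, with a synthetic-data module standing in for
the instruments so every stage can be exercised and validated without any
measurement.

## What it computes

**Global kinetic analysis.** A streak image is modelled as a sum of kinetic
components, each an exponential decay convolved with a Gaussian instrument
response function (IRF),

```
I(t, λ) = Σₙ  Aₙ(λ) · [ exp(−t/τₙ) ⊗ IRF(μ, σ) ]
```

where the lifetimes τₙ are shared across all wavelengths and all acquisition
time ranges (global analysis) and the decay-associated spectra (DAS) Aₙ(λ)
are solved exactly by linear least squares at every candidate lifetime
vector (variable projection). The convolution has the closed form
½·exp(σ²/2τ² − (t−μ)/τ)·erfc((σ/τ − (t−μ)/σ)/√2), evaluated through the
scaled complementary error function so that it never overflows. Sequential
(cascade) compartment models and the exact linear map between
evolution-associated and decay-associated spectra are provided alongside.

From a fit, the average time to charge separation is the amplitude-weighted
mean lifetime over the connected components,

```
τ_avCS = Σₙ τₙ·Aₙ / Σₙ Aₙ ,
```

with Aₙ the signed area under the n-th DAS. Components slower than a
threshold (default 1 ns) are classified as disconnected species (detached
antenna, free chlorophyll) and excluded.

**Steady-state spectra.** Normalization conventions (peak, Qy maximum,
red-tail integral), difference spectra, emission maxima with sub-grid
interpolation, and absorption band detection as minima of the
Savitzky–Golay second derivative.

**Fraction proteomics.** Per-fraction normalization factors computed from
the sums of non-normalized label-free protein intensities, per-protein
distributions across gradient bands, and enrichment calls (default: ≥75% of
a protein's signal in the target band).

**Pigments.** Response-factor-corrected conversion of HPLC peak areas to
mol per 100 chlorophylls, the vaucheriaxanthin response factor derived from
the violaxanthin one (+10%), and the Chl:Car ratio, with censored ("< x")
entries propagated as intervals.

## Worked example

Simulate the three streak-camera time ranges (0–155, 0–400, 0–1500 ps) with
the published four-component ground truth of the α-DM preparation, fit them
globally with the 6 ns free-chlorophyll lifetime fixed, and recompute the
trapping time:

```r
library(psitrap)

comp  <- psi_lhc_kinetics("alpha")
truth <- kinetic_ground_truth(lifetimes  = comp$lifetime,
                              das_shapes = default_das_shapes(comp$rel_amplitude),
                              fixed      = comp$fixed)
images <- gen_streak_set(truth, seed = 1)
fit <- fit_global(images, n_components = 4,
                  fixed = data.frame(index = 4, value = 6000),
                  restarts = 3, seed = 1)
tidy(fit)
#> # A tibble: 4 × 5
#>   component lifetime fixed amplitude rel_amplitude
#>       <int>    <dbl> <lgl>     <dbl>         <dbl>
#> 1         1     10.9 FALSE    0.332         0.332
#> 2         2     45.4 FALSE    0.486         0.487
#> 3         3   1529.  FALSE    0.0983        0.0984
#> 4         4   6000   TRUE     0.0822        0.0824

cls <- classify_components(fit)
average_decay_time(fit, included = which(cls$label == "connected"))
#> [1] 31.43443
```

The recovered lifetimes (10.9 ps, 45.4 ps, ~1.5 ns, 6 ns fixed) and relative
amplitudes (33%, 49%, 10%, 8%) match the generating values within noise, and
the trapping time of ~31 ps reproduces the published 31 ± 3 ps for the α-DM
supercomplex. `autoplot(fit)` draws the decay-associated spectra.

Band detection on a synthetic 77 K absorption spectrum recovers the four Qy
sub-bands:

```r
second_derivative_bands(gen_absorption())
#> # A tibble: 4 × 2
#>   position  depth
#>      <dbl>  <dbl>
#> 1     669. 0.0583
#> 2     679. 0.0447
#> 3     685. 0.0342
#> 4     698. 0.0189
```

and the pigment stoichiometry of the α-DM preparation gives

```r
chl_car_ratio(psi_lhc_pigments("alpha"))
#> # A tibble: 1 × 3
#>   estimate lower upper
#>      <dbl> <dbl> <dbl>
#> 1     3.16  3.16  3.16
```

i.e. a Chl:Car ratio of 3.2 at one decimal. `run_pipeline()` chains all
stages (simulation, fitting, spectra, fractions, pigments) from a single
seeded configuration and writes a JSON run report.

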