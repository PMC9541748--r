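---
title: "Reproductive investment curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproductive investment curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricurve)
```

## The model

`ricurve` treats an individual's yearly clutch sizes as a short time series
and asks over what temporal scale reproductive investment changes. The
series is demeaned and decomposed by the discrete Fourier transform with
one sample per year, giving candidate modes at frequency indices
$k = 1,\dots,\lfloor n/2 \rfloor$ with wavelength $n/k$ years. Each mode is
a *reproductive investment curve* (RIC). We summarize a mode by its
peak-to-trough amplitude $A_k$ — twice the mathematical half-amplitude —
because the biologically meaningful quantity is how much the clutch changes
between a good and a bad phase, in eggs. Two identities anchor the
implementation and are enforced by property tests: the mean plus all mode
sinusoids reconstructs the series to $10^{-9}$, and mode variance shares
sum to one (Parseval) for any non-constant series.

The *dominant* RIC is the mode with the largest $A_k$ (ties are broken
deterministically toward the longer wavelength); the *secondary* RIC is the
next largest. A dominant wavelength of exactly 2 years — the Nyquist
alternation, high clutch followed by low clutch — is classified
*short-term*, the carry-over analogue; anything longer is *long-term*, the
senescence analogue. A robustness variant classifies any wavelength under
4 years as short-term. A series needs at least three points to carry an
oscillatory signal, so shorter series are excluded at ingest, and a
constant series has no present modes and cannot be classified (such
individuals are dropped from classification with a count, which is why
sample sizes can differ slightly between the absolute and mean-centred
measures).

Two clutch measures flow through the same machinery: *absolute* clutch
size, and *mean-centred* clutch size (the individual's clutch minus the
population-year average over all first-clutch records). Centring removes
inter-annual environmental variation shared by the whole local population;
comparing results across the two measures separates environmental from
intrinsic oscillation.

## Ingest rules

Only first clutches of non-polygamous pairs enter the analysis: second and
replacement clutches reflect a different investment process within the same
season. Series must cover strictly consecutive breeding years — an interior
gap is more plausibly breeding outside the study area than an investment of
zero, so gapped individuals are dropped entirely rather than imputed.
Terminal truncation (death or emigration) never excludes an individual.
Population-year means are computed from **all** first-clutch records,
including individuals later dropped for gaps or short series: the
environmental baseline should use the full population sample, and the
focal individual's own record is included, as in standard centring.

## Inference

The binary dominant time-scale (0 = short-term, 1 = long-term) is fitted
with a logistic mixed model; short- and long-term RIC amplitudes with
Gaussian mixed models on a log scale (absolute measure) or square-root
scale (mean-centred measure, whose amplitudes can be legitimately near
zero). All models carry a birth-year random intercept and are fitted by
maximum likelihood (not REML) so that AICc is comparable across
fixed-effect structures. The candidate set is all $2^3$ subsets of
{mean individual clutch size, population, sex}. The parameter count $k$ in
AICc is the degrees of freedom of the maximized likelihood: fixed effects
plus the random-intercept variance, plus the residual variance for
Gaussian models — so the intercept-only binary model has $k = 2$.

Zero amplitudes are dropped (with an explicit count) before a log
transform; this is the mechanism by which the short-/long-amplitude model
sample sizes fall below the classification sample size. Models within
$\Delta\mathrm{AICc} < 2$ of the best are retained, their Akaike weights
renormalized, and coefficients averaged *conditionally* — a term is
averaged only over retained models that contain it. Full averaging
(omitted terms contribute zero) is available behind a flag; conditional is
the default and is recorded in the run metadata, since published
weighted-model averages rarely state which convention they use. Estimated
marginal means are computed from the single best-fitting model, not the
average: factors are averaged with equal level weights, covariates held at
their grand mean, random effects at zero, and predictions back-transformed
with delta-method standard errors (`emmeans` does this; the transforms are
written into the model formulas so back-transformation is automatic).

Singular fits (random-intercept variance estimated at the zero boundary)
are legitimate estimates and are kept; fits whose optimizer reports actual
non-convergence are excluded from the ranking with a warning.

## The simulator

`simulate_study()` generates breeding-record tables with known ground
truth. Each population configuration encodes a pace-of-life position:
annual adult survival (lifespans are geometric draws capped at nine
breeding years, the observed maximum age for yearly breeders of this
kind), a base clutch, a shared year effect per population-year, an
individual quality intercept, and two injected oscillations — a short-term
Nyquist alternation and a long-term wave with wavelength drawn from
{4, 6} years. One amplitude is drawn around each component's mean and the
larger draw is assigned to the individual's dominant component, so the
configured dominance probability is the ground truth. Clutches are rounded
half-up to whole eggs (switchable off for exact-recovery tests) and
floored at zero.

The `fast` preset (survival 0.45, within the 0.42–0.47 range reported for
deciduous-forest blue tit populations; large clutches; 70% dominant
long-term) and `slow` preset (survival 0.56, within 0.55–0.57 for
evergreen populations; small clutches; 30% dominant long-term) bracket the
published contrast. Amplitude means (3.0/1.8 eggs fast, 1.8/2.4 slow),
year-effect, quality and noise standard deviations (all 0.5 eggs) were
chosen as field-realistic values: together they give within-individual
clutch standard deviations around 1.5 eggs, typical of tit clutch records.

Two numerical subtleties surfaced in designing the generator and are worth
recording:

* **Nyquist phase.** A wavelength-2 cosine with free phase $\psi$ sampled
  yearly is $\cos(\psi)(-1)^t$: the realized alternation is attenuated by
  $|\cos\psi|$ and vanishes at $\psi = \pi/2$. The short-term component's
  phase is therefore drawn from $\{0, \pi\}$ only, so that the drawn
  amplitude is actually present in the sampled series and can serve as
  ground truth. The long-term phase stays uniform — non-Nyquist modes
  preserve amplitude under any phase.
* **Identifiability of the 2-year scale.** The wavelength grid is
  $\{n/k\}$, so an odd-length series has no candidate at exactly 2 years:
  a true alternator with a five-year lifespan is measured at wavelength
  2.5 and classified long-term under the default cutoff, and a three-year
  series has a single mode (wavelength 3) regardless of its dynamics.
  Dominant-scale recovery is therefore only a well-posed question on
  series with even length of at least four years, and exact recovery
  additionally requires the injected long wavelength to divide the
  lifespan (otherwise spectral leakage splits its energy across bins).
  Recovery tests and the acceptance summaries condition on this
  *identifiable subset* and report it explicitly.

## What passing tests do and do not show

With noise, rounding and year effects disabled, injected wavelengths and
peak-to-trough amplitudes are recovered exactly, and dominant-scale
classification on the identifiable subset is perfect — this validates the
spectral arithmetic. Under the presets' realistic noise, classification on
4–6 point series misassigns the dominant scale for roughly a quarter of
identifiable individuals, which attenuates the estimated fast–slow
difference in dominant-long prevalence to roughly half the configured
contrast. The acceptance checks therefore assert the *direction* of the
contrast and its detectability beyond pooled binomial Monte-Carlo error,
not its unattenuated magnitude; the attenuation itself is reported. Real
data add further departures the simulator does not emulate: age-dependent
mean investment, non-stationary oscillations, observation error in clutch
counts, and selective disappearance of heavy investors. Results on
simulated data validate the machinery, not the biology.

Problem sizes in the shipped tests and acceptance script — 500 simulated
individuals per population with three replicate studies for prevalence
recovery, 20 replicate fits of 800 observations for logistic recovery —
were chosen to keep binomial and Monte-Carlo error small relative to the
effects being recovered.

## Degenerate inputs and numerical choices

* Constant series: decomposition succeeds with zero present modes;
  classification refuses with an explicit error; cohort-level functions
  drop and count such individuals.
* A mode is "present" when $A_k > 10^{-9}$ eggs; zero-amplitude bins are
  placeholders, not strategies.
* The short-term cutoff is $\lambda \le 2 + 10^{-9}$: exactly the Nyquist
  mode, with tolerance only against floating-point wavelengths.
* No zero-padding, windowing, or detrending beyond demeaning: series are
  very short, and the raw-series reconstruction identity is part of the
  method's definition.
* Phase is computed and exported but never interpreted: the transform is
  non-directional, so an RIC says nothing about *when* within a lifetime
  peaks occur.
* AICc requires $n > k + 1$ and errors otherwise rather than returning an
  undefined correction.

## Limitations

The approach shares the constraint of all longitudinal life-history
analyses that individuals breeding fewer than three times are invisible,
and adds one of its own: the temporal resolution of the wavelength grid is
set by lifespan, so short-lived cohorts can only ever express coarse
scales, and the 2-year scale only at even lengths. Survival costs of
reproduction are out of scope — the pipeline models investment given
breeding, not the probability of surviving to breed.
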