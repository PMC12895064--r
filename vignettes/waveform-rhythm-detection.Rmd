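---
title: "Detecting non-sinusoidal rhythms in omics time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-sinusoidal rhythms in omics time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmfit)
library(dplyr)
```

## The problem

Abundances of transcripts, proteins and metabolites often oscillate — most
famously with the ~24 h day–night cycle — but many genuine biological
rhythms are not sinusoidal. Behavioural activity looks closer to a square
wave; transcripts driven by two promoters firing ~12 h apart show
asymmetric "cycloid" shapes; other molecules show short periodic impulses
from an otherwise stable baseline. A detector built only on a cosine will
either miss these features or parameterize them poorly.

`rhythmfit` fits four fixed waveform families per molecule and lets the
data choose among them:

* **harmonic** — the extended harmonic oscillator,
  $x(t) = A\,e^{\gamma t/2}\cos(\omega t + \phi) + y$. The exponential
  envelope makes amplitude change over the sampling window an explicit,
  interpretable parameter.
* **square** — a bounded two-component approximation of a digital
  square wave: the carrier plus a third harmonic with fixed relative
  amplitude 0.25,
  $x(t) = A\,e^{\gamma t/2}\,[\sin(\omega t + \phi) +
  0.25\sin(3\omega t + 3\phi)] + y$.
* **cycloid** — fundamental plus second harmonic,
  $x(t) = A\,e^{\gamma t/2}\,(-0.5)[\cos(2\omega t + 2\phi) -
  2\cos(\omega t + \phi)] + y$, i.e. a circadian component combined
  with an ultradian (~12 h) one, producing asymmetric crests.
* **transient** — a periodic gated Gaussian impulse: with cycle position
  $u = t \bmod (2\pi/\omega)$,
  $x(t) = A\,e^{-\frac{1}{2}\left(\frac{u - p_\tau}{\sigma}\right)^2} + y$
  when $u - p_\tau \ge 0$ and $y$ otherwise.

The component frequencies inside the square and cycloid models are
hard-locked multiples ($3\omega$, $2\omega$) of a single fitted
$\omega$, and the 0.25 / 0.5 / 2 coefficients are constants of the
model. This boundedness is deliberate: a free multi-harmonic regression
can fit almost anything, but the composite loses its mechanistic
reading. Four rigid shapes keep every selected model interpretable.

Two conventions are worth stating because the model family could be
written either way. First, the envelope exponent is $+\gamma t/2$, so
$\gamma < 0$ is a damped rhythm and $\gamma > 0$ a forced one; second,
the envelope multiplies the full two-component bracket of the square and
cycloid models, so $\gamma$ modulates the whole signal uniformly rather
than only the carrier. The transient carries no envelope at all, so no
regulatory class is reported for it.

## From fits to calls

For each feature (replicates enter as individual observations — no
averaging, which preserves error degrees of freedom):

1. **Fit** all four families by bounded nonlinear least squares
   (Levenberg–Marquardt). Frequency is bounded to a band around the
   expected period $T$: $\omega \in [2\pi/(T(1+\rho)),\,
   2\pi/(T(1-\rho))]$ with $\rho = 0.25$ by default; $|\gamma| \le
   6/t_{\max}$ so the envelope moves at most $e^{\pm 3}$ over the
   observed span (anything faster is an unidentifiable blow-up);
   $A \ge 0$ with sign absorbed into the phase; the impulse width is
   bounded to $[\Delta t/2,\ T(1+\rho)/4]$.
2. **Select** the family with the lowest sum of squared residuals
   (SSR). Exact ties resolve harmonic → square → cycloid → transient,
   simplest interpretation first. RMSE ($\sqrt{\mathrm{SSR}/n}$) is
   reported as the fit-quality measure.
3. **Test** the winner against its zero-amplitude reduction — the
   best-fit parameters with $A = 0$, which collapses every family to
   the constant $y$ — with a lack-of-fit F-test:
   $F = \frac{(\mathrm{SSR}_0 - \mathrm{SSR}_1)/q}{\mathrm{SSR}_1/(n-p)}$,
   $p = 5$, $q = p - 1 = 4$, referred to $F(q, n-p)$. The numerator
   degrees of freedom are $p-1$ because all shape parameters become
   inert when the amplitude is zero; only the baseline survives.
4. **Confirm** with Kendall's tau between observed and fitted values —
   a rank-level agreement check that punishes models whose variance is
   right but whose ordering is wrong.
5. **Adjust** both p-value families (F and tau) across all features of
   the batch with Benjamini–Hochberg, one family per statistic. A
   feature is **rhythmic** when both adjusted values fall below
   $\alpha$ (default 0.05). Reporting and adjusting both, and requiring
   both to pass, is the conservative reading of a filter-then-confirm
   pipeline; either raw p-value is available in the output for users
   who prefer one family.
6. **Classify** regulation from $\gamma$: below $-0.01\,h^{-1}$ damped,
   above $+0.01\,h^{-1}$ forced, otherwise stable. The default
   threshold corresponds to roughly a 27% envelope change over 48 h —
   about the smallest change visible by eye in a two-day course — and
   is exposed as an option.

Degenerate inputs are handled explicitly rather than by crashing:
constant series return an $A = 0$ fit and are never rhythmic;
noiseless perfect fits ($\mathrm{SSR}_1 = 0$) are flagged and called
rhythmic when the amplitude is non-negligible; features with fewer than
`min_obs` usable observations are skipped with a report and never abort
the batch.

## Numerical choices

The SSR surface is multimodal chiefly along the phase and the impulse
position. The fits therefore multi-start deterministically: eight
equispaced phases for the oscillatory families; for the transient, the
per-cycle argmax of the signal expanded by sub-interval offsets
($-\Delta t, -\Delta t/2, 0, +\Delta t/2$) and three width starts
($\Delta t/2, \Delta t, 2\Delta t$). The sub-interval expansion matters
because the onset gate makes the surface multimodal *between* sampling
points; with a single start the optimizer reliably parks on a sampling
time. Moment-based guesses seed the rest ($A_0 = (\max-\min)/2$,
$y_0$ = mean, $\gamma_0 = 0$, $\omega_0 = 2\pi/T$). Convergence uses
relative tolerance $10^{-8}$ with at most 5000 function evaluations per
start. There is no randomness anywhere in fitting, and observations are
sorted into a canonical order before fitting, so results are identical
for any input row order.

Z-score normalization per feature is on by default for multi-feature
tables (making calls invariant to affine rescaling of any feature) and
off for a single series, where raw units may be meaningful
(behavioural counts, for instance).

## What the simulator emulates — and what it does not

`simulate_panel()` generates labelled panels on a dense circadian
design: period 24 h, 48 h span (two full cycles), 2 h sampling, 2
replicates, i.i.d. Gaussian noise per observation. Defaults draw
$A \in [1,3]$, $\gamma \in \{-0.05, 0, 0.05\}$ (one damped, one stable,
one forced regime), $\phi \in [0, 2\pi)$, $y \in [-1,1]$,
$p_\tau \in [0, 24)$, $\sigma \in [1,3]$ h, plus flat `"null"` features
for the negative class. Gaussian noise matches the least-squares
objective; the generator does not emulate count overdispersion, batch
effects, missing-at-random structure, or autocorrelated noise, so green
tests certify the method's behaviour under its own assumptions, not
performance on any particular real dataset.

Two corners of this design are worth knowing about, because they are
properties of the study conditions rather than defects of the fit:

* An impulse whose onset $p_\tau$ falls inside the last sampling
  interval of the cycle is *invisible*: the gate hides the whole bump
  between grid points and the sampled series is exactly flat. Such a
  feature is unrecoverable in principle; the pipeline correctly returns
  a constant fit (and, on noiseless data, the SSR tie resolves to
  harmonic).
* A narrow impulse ($\sigma \lesssim \Delta t$) is sampled at only one
  or two points per cycle, so amplitude, width and position trade off
  along a flat likelihood ridge; the amplitude estimate is then highly
  variable even when the optimizer finds the global optimum. Period and
  detection are much more robust than amplitude in this regime. Denser
  sampling, not more iterations, is the cure.

## Problem sizes used in the checks

The shipped tests exercise: evaluator-vs-oracle agreement at hundreds
of random parameter draws; parameter recovery on 50 noisy simulations
per family; model selection on 100-feature panels (noiseless and at 5%
amplitude-proportional noise); false-positive control on a 1000-feature
null panel end to end; and determinism/order-invariance on full result
tables. These sizes give stable rates while keeping a full run in
minutes on one core.

## A worked example

```{r example, eval = FALSE}
panel <- simulate_panel(n_per_class = 25, noise_prop = 0.05, seed = 7)
calls <- detect_rhythms(panel$data)

count(calls, best_model, rhythmic)
plot_rhythm_summary(calls)

# single-feature view
fit <- calls$fit[[which(calls$feature_id == "cycloid_001")]]
autoplot(fit)
tidy(fit)
```

## Limitations

Only the four fixed families are fitted — this is not a general Cosinor
with user-chosen harmonic counts, and the ultradian component of the
cycloid is hard-locked at $2\omega$ rather than searched. One expected
period is analysed per run; free-running period drift across days is out
of scope, as is differential rhythmicity between conditions. The F-test
p-value is computed conditional on the selected family; with four
candidate models the raw p-values of null features are mildly optimistic,
which is why the pipeline's operating characteristics are asserted at the
batch level (BH-adjusted false-call rate on null panels) rather than on
raw p-values.
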