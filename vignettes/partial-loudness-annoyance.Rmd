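---
title: "Modelling combined aircraft and road-traffic noise annoyance with partial loudness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling combined aircraft and road-traffic noise annoyance with partial loudness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoymap)
```

## The problem

Residents near airports are usually exposed to aircraft and road-traffic
noise at the same time. Two features make combined exposure hard to assess
with ordinary level-based indicators. First, at equal A-weighted level,
aircraft noise is more annoying than road noise, largely because of its
spectral content; a perceptual magnitude — loudness — captures this, a level
in dBA does not. Second, the sources partially mask one another: a steady
road hum reduces the perceived loudness of an aircraft flyover, and a loud
flyover can render the road inaudible. `annoymap` quantifies both effects
with a partial-loudness model and carries them through to community
annoyance: an 11-point short-term rating model, a long-term
percent-highly-annoyed (%HA) model, and per-source annoyance rasters.

## The loudness chain

The core follows the Moore–Glasberg family of loudness models.

**Excitation patterns.** A stationary stimulus is described by its
1/3-octave band spectrum (25 Hz–12.5 kHz). Each band is treated as a single
component at its center frequency. Component levels pass through a combined
outer/middle-ear transfer and are spread over a grid of auditory channels
spaced 0.25 Cam apart on the ERB-rate scale (1.75–39 Cams, roughly
50 Hz–15 kHz) using rounded-exponential filter skirts whose lower slope
flattens with level. The transfer is constructed so that a tone at the
free-field hearing threshold produces exactly the threshold excitation
`E_THRQ` of its channel.

**Specific loudness.** Excitation `E` maps to loudness density (sones/Cam)
by the compressive law

\[ N' = C\,[(E\,G + A)^\alpha - A^\alpha], \]

with a `(2E/(E+E_THRQ))^{1.5}` attenuation below the absolute threshold and
a square-root high-level branch above an excitation of $10^{10}$. The
cochlear-amplifier gain `G` is maximal and constant for channels at and
above 500 Hz and falls to −25 dB at 50 Hz; `alpha`, `A` and `E_THRQ`
co-vary with it. Total loudness is the integral of `N'` over the Cam scale.

**Partial loudness.** When a target and a background are present together,
the background raises the target's detection threshold to
`E_THRN = K·E_bg + E_THRQ`, where `K` is the frequency-dependent
signal-to-noise ratio at masked threshold (≈13 dB at 50 Hz, ≈−3 dB at
2 kHz and above). For a target at or above this masked threshold,

\[ N'_{tgt} = C[((E_{sig}+E_{bg})G + A)^\alpha - A^\alpha]
  - C[((E_{bg}(1{+}K)+E_{THRQ})G + A)^\alpha - (E_{THRQ}G + A)^\alpha]
    \left(\tfrac{E_{THRN}}{E_{sig}}\right)^{0.3}. \]

At the masked threshold this reduces exactly to the loudness of a tone at
the absolute threshold in quiet; below it, the value decays with the same
`(2E/(E+E_THRN))^{1.5}` factor as the unmasked low-level branch and is
continuous at the threshold. Both branches collapse onto the unmasked
formula when the background is silent — the package routes those channels
through the identical code path, so the no-masker identity is exact to the
bit. Partial loudness is clamped to `[0, unmasked]`: partial masking cannot
increase loudness. Total loudness of a combination assumes additivity of
the partial specific loudnesses of its components; the package exposes all
three quantities (target-partial, background, total).

**Binaural inhibition.** The signal in one ear inhibits the response in the
other. Each ear's specific loudness is divided by the effective factor

\[ \mathrm{INH} = \frac{2}{(1 + \mathrm{sech}(S_{contra}/S_{ipsi}))^{P}},
   \qquad P = 1.598, \]

where the ratio uses patterns smoothed across the Cam axis (two-sided
exponential kernel, width 2 Cams by default). With a silent contralateral
ear the factor is $2^{1-P} \approx 0.661$; for identical ears it is
$\approx 0.900$. Dividing by these factors makes diotic loudness about 1.5
times — not twice — the monaural value, and calibrates so a 1-kHz tone at
40 dB SPL presented diotically is 1 sone. The scaling constant
`C = 0.042575` was fixed once from that anchor with the package's own
tables; loudness then doubles per ~10 dB between 40 and 80 dB SPL:

```{r anchors}
sapply(c(40, 50, 60, 70), function(l)
  loudness_stationary(third_octave_spectrum(1000, l)))
```

**Time-varying loudness.** Waveforms are analysed in 50-ms Hann frames with
a 10-ms hop; per-frame band levels run through the stationary chain to give
instantaneous loudness, which is smoothed by two attack/release AGC stages
(short-term 22/50 ms, long-term 99/2000 ms). The maximum of the long-term
series is the representative loudness of a nonstationary sound. A 1-ms hop
would oversample these time constants considerably; 10 ms resolves them
comfortably at a fraction of the cost and is configurable.

### Numerical notes

* Constants tables (`G`, `A`, `alpha`, `E_THRQ`, `K`, ear transfer) are
  smooth parameterizations of the reference model's published behaviour,
  not verbatim standard tables; everything is overridable through
  `loudness_constants()` and serializable with `constants_to_file()`.
* Where the ipsilateral smoothed pattern is zero the binaural ratio is
  undefined; the output is defined as zero (no loudness to inhibit).
* Band levels are validated below 120 dB SPL; excitations above $10^{10}$
  use the high-level branch in the unmasked path.
* Bisection in the equal-loudness matcher uses the bracket
  `[reference − 5 dB, ceiling]` with a 0.05-dB tolerance, where the ceiling
  keeps every band below 120 dB SPL; a background so intense that the
  target cannot reach the match inside the bracket raises an explicit
  error.

## Equal-loudness matching

The matcher answers the question posed in an adaptive up–down experiment:
at what level is a target with background as loud as the target at a
reference level in quiet? Because masking only reduces loudness, the match
is at or above the reference. The matching statistic is the target's
integrated stationary partial loudness; for a flyover-like target the
representative (max long-term) loudness occurs at the envelope peak, about
`10·log10(8/3) ≈ 4.26 dB` above the file's LAeq for the synthetic
raised-cosine envelope, which `target_crest_db` expresses without a full
time-varying computation:

```{r match}
equal_loudness_table(aircraft_template(), road_template(),
                     c(68, 73, 78), c(55, 65, 75),
                     target_crest_db = flyover_crest_db())
```

Shifts grow as the background rises and shrink as the target rises — the
qualitative pattern of the matching experiment. With a background more than
20 dB below the flyover target, the shift stays under a decibel.

`simulate_staircase()` emulates the adaptive procedure itself: 5→3→2→1 dB
steps shrinking at reversals, a response-noise SD in dB, and a "same"
response when the loudness difference falls below a just-noticeable
fraction (2 % of the reference loudness by default). That window is
narrower than the final 1-dB step, so a noiseless track can oscillate
around the match; a bounded number of final-step trials closes the track
with "same", leaving the converged level within one step of the analytic
match.

## Annoyance models

Both exposure–response curves are three-parameter logistics written in
reciprocal form $f(x) = 1/(1/L + a\,b^x)$ (equivalently
$L/(1+e^{-k(x-x_0)})$):

* short-term rating (0–10 ICBEN scale): $1/(0.1 + 0.463\cdot 0.936^{N})$,
  rising from ≈1.8 at zero loudness toward 10;
* long-term %HA: $1/(0.01 + 0.043\cdot 0.97^{N})$, ≈18.9 % at zero
  loudness — some residents report high annoyance regardless of modelled
  exposure — rising toward 100 %.

The printed sources render these fractions ambiguously; the reciprocal
reading is adopted because it is exactly the bounded logistic with maxima
matching the rating scale (10) and a percentage (100), and it reproduces
the stated nonzero %HA at zero loudness. "Highly annoyed" means a rating of
at least 8 (the top three categories, the conventional top-27 % cut); the
cutoff is an argument where it matters.

`fit_logistic()` fits the reciprocal form by Levenberg–Marquardt
(`minpack.lm`), initializing the maximum at the scale maximum (10 or 100)
and bounding it there from above, with `b` started from a log-linear
regression. Recovery is exact on noiseless data and unbiased under
response noise; `scripts/acceptance.R` demonstrates both refits.

## RLS-90 road emission

The road-traffic chain implements the guideline emission formulas: the
idealized 25-m emission level `37.3 + 10 log10(Q(1+0.082P))`, the
speed-limit correction (zero at the 100/80 km/h reference for any truck
share), the gradient correction (`0.6g − 3` above 5 %), user-supplied
surface/propagation corrections, the intersection surcharge, and energetic
multi-lane combination. Geometric propagation (barriers, topography) is a
noise-mapping program's job and out of scope; a simple
distance-attenuation helper exists only to build toy grids.

## Synthetic data

The generator supplies every input the pipeline needs, deterministically
under a seed:

* **Templates** (`aircraft_template()`, `road_template()`): fixed 1/3-octave
  shapes, calibrated to a requested dBA. The aircraft shape keeps the
  substantial low-frequency energy of a real flyover with a broad 1–8 kHz
  plateau (its high-frequency character relative to traffic); the road
  shape has a low-frequency plateau and declines within a 15-dB window
  over 100 Hz–5 kHz. The shapes were chosen from typical published
  flyover/traffic spectra such that the equal-loudness predictions
  reproduce the matching experiment's pattern (weak masking at ≥20 dB
  separation); the recordings they stand in for are not public, so the
  templates are explicitly approximate.
* **Flyover waveforms**: template-shaped noise under a raised-cosine
  envelope peaking mid-file, partially decorrelated across ears, calibrated
  in LAeq.
* **Jury**: the 85-condition design (5 aircraft alone, 5 road alone, 25
  aircraft-with-road, 25 road-with-aircraft, 25 combined; levels
  63–83 × 55–75 dBA in 5-dB steps), condition loudness via the loudness
  chain, ratings = short-term model + Gaussian subject noise (SD 0.5 scale
  points by default — the experiment reports no inter-subject variance, so
  a half-point spread was chosen once as typical of 11-point rating data),
  rounded and clipped.
* **Survey**: respondents drawn over an exposure grid; indoor levels
  (−15 / −15.8 dBA for aircraft / road, slightly open window), loudness
  triple per cell, highly-annoyed flags Bernoulli from the long-term curve,
  exposure groups (<50, 50–60, 60–70, >70 dBA).
* **Toy grids**: a line-source road and a perpendicular flight track on a
  10-m grid with configurable dB-per-doubling decay.

What passing tests on these data do show: the pipeline's internal
consistency — calibration anchors, masking monotonicity and asymmetry,
additivity in the strong-target limit, parameter recovery of both fitted
curves from their own simulations. What they cannot show: agreement with
human listeners or residents, which requires the original recordings,
ratings and GIS maps.

## Annoyance mapping

`annoyance_surface()` turns paired aircraft/road LAeq rasters into six
layers: three loudness surfaces (aircraft-partial with road as background,
road-partial with aircraft as background, total) and their %HA images under
the long-term model. Cells are treated as stationary (annual-average LAeq
inputs justify steady-state treatment) and indoor corrections are applied
before loudness, mirroring the long-term model's construction. Indoor
levels below 0 dBA contribute no excitation.

```{r map}
g <- receiver_grid(nx = 8, ny = 8, road_level = 75, air_level = 80)
ag <- annoyance_surface(g)
round(ag$layers$pct_ha_aircraft, 1)[1:4, 1:4]
```

The signature feature is the background-noise effect: cells near the road
show suppressed aircraft %HA at equal aircraft exposure, and the effect is
asymmetric — a loud flyover annihilates the road's partial loudness while
the reverse suppression is mild.

## Known limitations

* The constants tables are approximations of the reference model's
  published tables; absolute loudness values carry that uncertainty even
  though the calibration anchors are enforced.
* Partial loudness of time-varying mixtures is approximated stationarily
  (crest-corrected) in the matcher; a frame-by-frame partial-loudness trace
  is not implemented.
* The spectrum templates are qualitative stand-ins; conclusions about any
  real site require its own spectra and maps.
* The long-term model inherits the survey's context; transferring it to
  other regions is an open question of the underlying study, not of this
  implementation.
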