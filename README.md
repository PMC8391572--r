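# annoymap

Combined transportation noise annoyance from partial loudness.

People living near airports hear aircraft and road traffic at once. Neither
source's A-weighted level predicts the community response on its own: at equal
level, aircraft noise is the more annoying, and each source partially masks
the other, so the annoyance attributable to one source depends on the other.
`annoymap` models both effects through loudness:

* **Loudness core** — a stationary and time-varying loudness model of the
  Moore–Glasberg lineage: excitation patterns on an ERB-spaced channel grid,
  compressive specific loudness `N' = C[(E G + A)^α − A^α]`, **partial**
  specific loudness of a target under a masking background (masked threshold
  `E_THRN = K·E_bg + E_THRQ`, correction weighted by `(E_THRN/E_sig)^0.3`),
  and **binaural inhibition**
  `INH = 2 / (1 + sech(S_contra/S_ipsi))^1.598`, which makes diotic loudness
  ≈1.5× monaural and anchors 1 sone at a 1-kHz, 40-dB-SPL diotic tone.
* **Equal-loudness matching** — predicts the level at which a target with
  background is as loud as the target in quiet (bisection on partial
  loudness) and simulates the adaptive 5→1-dB up–down procedure.
* **Annoyance models** — reciprocal-form logistics `1/(1/L + a·b^x)` linking
  loudness to the mean 0–10 rating (`1/(0.1 + 0.463·0.936^N)`) and to the
  long-term percentage highly annoyed (`1/(0.01 + 0.043·0.97^N)`), plus a
  Levenberg–Marquardt fitter, %HA tabulation (rating ≥ 8) and 5-sone
  loudness binning.
* **RLS-90 road emission** — `Lm,E = 37.3 + 10 log10(Q(1+0.082P))` with the
  speed-limit and gradient corrections and energetic lane combination.
* **Synthetic data** — deterministic aircraft/road template spectra, flyover
  waveforms, the 85-condition jury design, simulated ratings and surveys,
  and toy exposure grids, so the whole pipeline runs with no external data.
* **Annoyance mapping** — per-cell indoor correction (−15 / −15.8 dBA),
  loudness triple (aircraft-partial, road-partial, total) and %HA rasters
  that show the background-noise effect ordinary noise maps cannot.

## Worked example

```r
library(annoymap)

# loudness of a 73-dBA flyover spectrum, alone and over a 65-dBA road
loudness_stationary(aircraft_spectrum(73))                        # 43.35 sones
partial_loudness_stationary(aircraft_spectrum(73), road_spectrum(65)) # 27.20 sones

# the masking cuts the predicted short-term annoyance rating
short_term_annoyance(c(43.35, 27.20))                             # 7.92 -> 5.66

# level at which the flyover over the road sounds as loud as 73 dBA in quiet
predict_equal_level(aircraft_template(), road_template(), 73, 65,
                    target_crest_db = flyover_crest_db())         # 76.5 dBA

# one map cell: outdoor 70 dBA aircraft + 65 dBA road
cell_loudness(70, 65)   # aircraft 8.96, road 0.13, total 16.52 sones
long_term_pct_ha(16.52) # 27.8 % highly annoyed
```

The first two lines quantify partial masking: the road background strips a
third of the flyover's loudness, which translates to about 2.3 points on the
11-point annoyance scale and a 3.5-dB equal-loudness shift. In the map cell,
the road indoors is almost completely masked by the aircraft (0.13 sones
against its unmasked value), the asymmetry that makes per-source annoyance
maps informative.

A command-line wrapper with `loudness`, `match`, `fit`, `map` and `simulate`
subcommands is installed at `inst/scripts/annoymap` (see `?run_cli`).

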