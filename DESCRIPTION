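Package: annoymap
Title: Combined Transportation Noise Annoyance from Partial Loudness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models community annoyance from combined aircraft and road-traffic
    noise using a partial-loudness model with binaural inhibition. Computes
    excitation patterns and (partial) specific loudness from 1/3-octave band
    spectra or calibrated binaural waveforms, predicts equal-loudness level
    matches under background noise, fits logistic exposure-response models for
    short-term annoyance ratings and the long-term percentage of highly annoyed
    residents, evaluates RLS-90 road-traffic emission levels, and renders
    per-source percent-highly-annoyed annoyance rasters that expose the
    background-noise (masking) effect between sources. Includes a synthetic-data
    generator for stimuli, jury ratings, survey responses and toy exposure
    grids so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
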