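# shared fixtures: one constants bundle for the whole suite (grid build is
# cheap but repeated everywhere), a pure-tone spectrum helper, and a flat
# broadband shape used by the masking/additivity checks
cst <- loudness_constants()

tone_spec <- function(level_db, freq = 1000) third_octave_spectrum(freq, level_db)

flat_spec <- function(level_db,
                      freqs = c(125, 250, 500, 1000, 2000, 4000)) {
  third_octave_spectrum(freqs, rep(level_db, length(freqs)))
}

# diotic loudness of a specific-loudness pattern pair (both ears identical)
diotic_sones <- function(S, constants = cst) {
  pair <- binaural_inhibition(S, S, constants)
  integrate_loudness(pair$left) + integrate_loudness(pair$right)
}
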