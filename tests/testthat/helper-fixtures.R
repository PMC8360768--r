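# Shared fixtures, built once per test run (the background and stimulus
# battery are deterministic and moderately expensive).

.fixtures <- new.env(parent = emptyenv())

fixture_background <- function() {
  if (is.null(.fixtures$bg)) .fixtures$bg <- make_background()
  .fixtures$bg
}

fixture_battery <- function() {
  if (is.null(.fixtures$battery)) {
    .fixtures$battery <- design_stimulus_battery(fixture_background())
  }
  .fixtures$battery
}

# a zero-contrast square-wave waveform (constant background drives)
fixture_flat_waveform <- function(n_cycles = 1) {
  key <- paste0("flat", n_cycles)
  if (is.null(.fixtures[[key]])) {
    sol <- solve_silent_substitution(fixture_background(), contrast_spec())
    .fixtures[[key]] <- build_square_wave(sol, fixture_background(),
                                          n_cycles = n_cycles)
  }
  .fixtures[[key]]
}

# a single neuron wrapped as a population-like list
one_unit <- function(spec) list(spec)

# spike subset helper
unit_spikes <- function(spikes, uid) spikes[spikes$unit_id == uid, , drop = FALSE]
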