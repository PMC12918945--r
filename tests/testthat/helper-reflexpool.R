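# Shared helpers: small deterministic fixtures built in code.

# perfectly periodic spike train at `dr` Hz
periodic_train <- function(dr, duration, phase = 0) {
  isi <- 1000 / dr
  spike_train(seq(phase + isi, duration, by = isi), duration)
}

# stimulus onsets guaranteed to have full pre-windows
regular_stimuli <- function(n, isi = 1000, start = 1000) {
  structure(seq(start, by = isi, length.out = n), class = "stimulus_train")
}

# constant-current membrane simulation shortcut
tonic_spikes <- function(params, current, duration, dt = 0.05) {
  simulate_mn(params, rep(current, round(duration / dt)), dt,
              record_voltage = FALSE)$spike_times
}
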