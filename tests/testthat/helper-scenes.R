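# Shared fixture builders: everything is generated in code at test time.

# Minimal one-row population for hand-built spike trains.
one_neuron <- function(pos = c(0, 0, 10), soma_amplitude = 200,
                       indicator_positive = TRUE, baseline_rate = 0,
                       burst_rate = 0) {
  data.frame(id = 1, x = pos[1], y = pos[2], z = pos[3],
             indicator_positive = indicator_positive,
             opsin_connected = FALSE,
             baseline_rate = baseline_rate, burst_rate = burst_rate,
             burst_min = 4, burst_max = 4,
             soma_amplitude = soma_amplitude)
}

manual_trains <- function(times, duration, id = 1) {
  tr <- stats::setNames(list(sort(times)), as.character(id))
  attr(tr, "duration") <- duration
  class(tr) <- "spike_trains"
  tr
}

# Wrap a numeric vector as a dF/F trace (already normalized).
as_dff <- function(values, fs = 60) {
  structure(list(values = values, sampling_rate = fs, F0 = NULL,
                 filter_settings = NULL), class = "dff_trace")
}

as_recording <- function(mat, fs = 30000, sites = NULL) {
  structure(list(samples = as.matrix(mat), sampling_rate = fs,
                 electrode_sites = sites, d0 = 20, noise_sd = NA_real_),
            class = "extracellular_recording")
}

# Noiseless single-transient photodiode trace.
render_single_burst <- function(n_spikes, t0 = 100, isi = 7.5e-3,
                                duration = 200, kinetics = calcium_kinetics(),
                                noise = FALSE, seed = 1) {
  pop <- one_neuron()
  times <- t0 + (seq_len(n_spikes) - 1) * isi
  tr <- manual_trains(times, duration)
  render_calcium_current(tr, pop, kinetics, duration = duration,
                         noise = noise, seed = seed)
}

# Closed-form unitary kernel facts used as oracles.
kernel_peak_time <- function(kinetics) {
  kinetics$tau_rise * log(1 + kinetics$tau_decay / kinetics$tau_rise)
}
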