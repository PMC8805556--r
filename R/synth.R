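#' Synthetic population configuration
#'
#' Parameters of the ground-truth neuron population the generator draws:
#' counts, the fraction expressing the calcium indicator (e.g. under a
#' CaMKIIa promoter), the fraction of indicator-positive neurons that are
#' rate-modulated by upstream optogenetic stimulation, firing-rate and burst
#' parameter ranges, spike amplitudes at the soma, and the spatial box the
#' somata occupy above the probe.
#'
#' Defaults describe the reference six-neuron scene: four indicator-positive
#' neurons (two of six negative), all positives coupled to stimulation,
#' low-rate tonic firing with a superimposed burst process whose bursts drive
#' detectable calcium transients.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param fraction_positive Indicator-positive fraction; exactly
#'   `round(n_neurons * fraction_positive)` neurons get the flag.
#' @param fraction_connected Fraction of indicator-positive neurons whose
#'   rate follows the stimulation.
#' @param baseline_rate_range Tonic Poisson rate range (Hz).
#' @param burst_rate_range Burst-onset Poisson rate range (bursts/s).
#' @param burst_size_range Spikes per burst, discrete uniform (min >= 2).
#' @param soma_amplitude_range Extracellular spike amplitude at zero
#'   electrode distance (uV).
#' @param box 2 x 3 matrix `rbind(lower, upper)` of the soma box (um) in the
#'   probe frame.
#' @param min_separation Minimum pairwise soma distance (um), enforced by
#'   rejection.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_neurons = 6,
                         fraction_positive = 4 / 6,
                         fraction_connected = 1,
                         baseline_rate_range = c(0.8, 2),
                         burst_rate_range = c(0.15, 0.2),
                         burst_size_range = c(4, 8),
                         soma_amplitude_range = c(180, 320),
                         box = rbind(c(-40, -75, 5), c(40, 75, 30)),
                         min_separation = 45) {
  stopifnot(n_neurons >= 1, fraction_positive >= 0, fraction_positive <= 1,
            fraction_connected >= 0, fraction_connected <= 1,
            burst_size_range[1] >= 2, all(baseline_rate_range >= 0))
  box <- as.matrix(box)
  stopifnot(nrow(box) == 2, ncol(box) == 3, all(box[2, ] >= box[1, ]))
  if (all(box[2, ] == box[1, ]))
    stop("config error: spatial box is empty", call. = FALSE)
  structure(list(n_neurons = as.integer(n_neurons),
                 fraction_positive = fraction_positive,
                 fraction_connected = fraction_connected,
                 baseline_rate_range = baseline_rate_range,
                 burst_rate_range = burst_rate_range,
                 burst_size_range = burst_size_range,
                 soma_amplitude_range = soma_amplitude_range,
                 box = box, min_separation = min_separation),
            class = "synth_config")
}

#' Generate a ground-truth neuron population
#'
#' Draws a reproducible population from a [synth_config()]: soma positions
#' uniform in the box (with a minimum-separation rejection step), exactly
#' `round(n * fraction_positive)` indicator-positive neurons, stimulation
#' coupling drawn among the positives, and per-neuron rate/burst/amplitude
#' parameters uniform in their configured ranges.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical
#'   populations.
#' @return A data frame with one row per neuron: `id`, `x`, `y`, `z`,
#'   `indicator_positive`, `opsin_connected`, `baseline_rate`, `burst_rate`,
#'   `burst_min`, `burst_max`, `soma_amplitude`.
#' @export
generate_population <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_neurons
  with_seed(seed, {
    box <- config$box
    pos <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      for (try in 1:2000) {
        cand <- runif(3, box[1, ], box[2, ])
        if (i == 1) { pos[i, ] <- cand; break }
        d <- sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - cand)^2))
        if (all(d >= config$min_separation) || try == 2000) {
          pos[i, ] <- cand; break
        }
      }
    }
    n_pos <- round(n * config$fraction_positive)
    positive <- rep(FALSE, n)
    positive[sample.int(n, n_pos)] <- TRUE
    connected <- positive & (runif(n) < config$fraction_connected)
    data.frame(
      id = seq_len(n),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      indicator_positive = positive,
      opsin_connected = connected,
      baseline_rate = runif(n, config$baseline_rate_range[1],
                            config$baseline_rate_range[2]),
      burst_rate = runif(n, config$burst_rate_range[1],
                         config$burst_rate_range[2]),
      burst_min = config$burst_size_range[1],
      burst_max = config$burst_size_range[2],
      soma_amplitude = runif(n, config$soma_amplitude_range[1],
                             config$soma_amplitude_range[2]))
  })
}

#' Optical stimulation schedule
#'
#' Periodic square-wave stimulation: default 0.5 Hz with a 25% duty cycle at
#' 100 uW, the configuration used to drive the upstream opsin-expressing
#' population.
#'
#' @param frequency Cycle frequency (Hz), > 0.
#' @param duty ON fraction of each cycle, in (0, 1).
#' @param power Optical power (uW).
#' @param t_start,t_end Schedule span (s).
#' @return A `stim_schedule` list.
#' @export
stim_schedule <- function(frequency = 0.5, duty = 0.25, power = 100,
                          t_start = 0, t_end = 60) {
  stopifnot(frequency > 0, duty > 0, duty < 1, t_end > t_start)
  structure(list(frequency = frequency, duty = duty, power = power,
                 t_start = t_start, t_end = t_end),
            class = "stim_schedule")
}

#' Cycle ON/OFF windows of a stimulation schedule
#'
#' @param schedule A [stim_schedule()].
#' @return Data frame with per-cycle `on_start`, `on_end`, `off_end`.
#' @export
stim_cycles <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  period <- 1 / schedule$frequency
  starts <- seq(schedule$t_start, schedule$t_end - period, by = period)
  if (length(starts) == 0)
    return(data.frame(on_start = numeric(0), on_end = numeric(0),
                      off_end = numeric(0)))
  data.frame(on_start = starts,
             on_end = starts + schedule$duty * period,
             off_end = starts + period)
}

stim_is_on <- function(t, schedule) {
  if (is.null(schedule)) return(rep(FALSE, length(t)))
  period <- 1 / schedule$frequency
  inside <- t >= schedule$t_start & t < schedule$t_end
  phase <- (t - schedule$t_start) %% period
  inside & phase < schedule$duty * period
}

#' Generate spike trains for a population
#'
#' Inhomogeneous-Poisson tonic firing (rate multiplied by `stim_gain` during
#' stimulation ON phases for opsin-connected neurons only) with a
#' superimposed burst process: burst onsets Poisson at each neuron's burst
#' rate, burst sizes discrete-uniform in the configured range, within-burst
#' inter-spike intervals uniform in 5-10 ms. An absolute refractory period is
#' enforced by deleting the later spike of any closer pair.
#'
#' For indicator-positive neurons - the excitatory ensemble - a fraction
#' `burst_sync` of each neuron's bursts is drawn by thinning one shared
#' population-event process, emulating synchronous population bursts; the
#' rest are private. Thinning a Poisson process leaves each neuron's
#' marginal burst process Poisson at exactly its configured rate, so
#' `burst_sync` controls cross-neuron burst correlation without changing
#' any rate. Indicator-negative neurons always burst independently.
#'
#' @param population From [generate_population()].
#' @param schedule Optional [stim_schedule()]; `NULL` means no stimulation.
#' @param duration Recording duration (s), > 0.
#' @param stim_gain Tonic-rate multiplier during ON phases for connected
#'   neurons (>= 1).
#' @param seed Integer seed.
#' @param refractory Absolute refractory period (s).
#' @param burst_sync Fraction of each indicator-positive neuron's bursts
#'   coming from the shared population-event process, in \[0, 1\].
#' @return A list (class `spike_trains`) of numeric vectors of strictly
#'   increasing spike times, named by neuron id.
#' @export
generate_spike_trains <- function(population, schedule = NULL,
                                  duration = 60, stim_gain = 1, seed = 1,
                                  refractory = 2e-3, burst_sync = 0.9) {
  stopifnot(duration > 0, stim_gain >= 1, burst_sync >= 0, burst_sync <= 1)
  with_seed(seed, {
    pos_rates <- population$burst_rate[population$indicator_positive]
    mother_rate <- if (length(pos_rates) && burst_sync > 0)
      burst_sync * max(pos_rates) else 0
    mother <- if (mother_rate > 0)
      sort(runif(rpois(1, mother_rate * duration), 0, duration))
    else numeric(0)
    neuron_seeds <- sample.int(.Machine$integer.max, nrow(population))
    trains <- lapply(seq_len(nrow(population)), function(i) {
      nrn <- population[i, ]
      with_seed(neuron_seeds[i], {
        gain <- if (isTRUE(nrn$opsin_connected)) stim_gain else 1
        rmax <- nrn$baseline_rate * gain
        tonic <- numeric(0)
        if (rmax > 0) {
          n_cand <- rpois(1, rmax * duration)
          cand <- sort(runif(n_cand, 0, duration))
          r <- nrn$baseline_rate *
            ifelse(stim_is_on(cand, schedule) &
                     isTRUE(nrn$opsin_connected), stim_gain, 1)
          tonic <- cand[runif(n_cand) < r / rmax]
        }
        onsets <- numeric(0)
        if (nrn$burst_rate > 0) {
          if (isTRUE(nrn$indicator_positive) && mother_rate > 0) {
            keep <- runif(length(mother)) <
              burst_sync * nrn$burst_rate / mother_rate
            shared <- mother[keep]
            private_rate <- (1 - burst_sync) * nrn$burst_rate
            private <- sort(runif(rpois(1, private_rate * duration),
                                  0, duration))
            onsets <- sort(c(shared, private))
          } else {
            onsets <- sort(runif(rpois(1, nrn$burst_rate * duration),
                                 0, duration))
          }
        }
        bursts <- unlist(lapply(onsets, function(t0) {
          size <- nrn$burst_min +
            sample.int(nrn$burst_max - nrn$burst_min + 1, 1) - 1
          cumsum(c(t0, runif(size - 1, 5e-3, 10e-3)))
        }))
        ts <- sort(c(tonic, bursts))
        ts <- ts[ts < duration]
        # refractory thinning: drop spikes inside the dead time of the
        # previous kept spike
        if (length(ts) > 1) {
          keep <- rep(TRUE, length(ts))
          last <- ts[1]
          for (k in 2:length(ts)) {
            if (ts[k] - last < refractory) keep[k] <- FALSE else last <- ts[k]
          }
          ts <- ts[keep]
        }
        ts
      })
    })
    names(trains) <- population$id
    structure(trains, class = "spike_trains", duration = duration)
  })
}

#' GCaMP6f-like calcium transient kinetics
#'
#' Double-exponential unitary transient with linear spike summation. The
#' kernel is normalized so its peak equals `unitary_dff`, which makes the
#' configured unitary amplitude, the spike-count regression slope, and the
#' burst-detectability arithmetic directly comparable.
#'
#' @param tau_rise Rise time constant (s); default 0.05.
#' @param tau_decay Decay time constant (s); default 0.4. Must exceed
#'   `tau_rise`.
#' @param unitary_dff Peak dF/F of a single spike; default 0.01.
#' @return A `calcium_kinetics` list.
#' @export
calcium_kinetics <- function(tau_rise = 0.05, tau_decay = 0.4,
                             unitary_dff = 0.01) {
  if (!(tau_rise > 0 && tau_decay > tau_rise && unitary_dff > 0))
    stop("invalid kinetics: need 0 < tau_rise < tau_decay, unitary_dff > 0",
         call. = FALSE)
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 unitary_dff = unitary_dff),
            class = "calcium_kinetics")
}

#' Unitary calcium kernel
#'
#' Peak-normalized double exponential
#' `unitary_dff * (1 - exp(-t/tau_rise)) * exp(-t/tau_decay) / peak` for
#' `t >= 0`, zero before. The unnormalized shape peaks at
#' `t* = tau_rise * log(1 + tau_decay / tau_rise)`.
#'
#' @param t Times since the spike (s).
#' @param kinetics A [calcium_kinetics()].
#' @return dF/F contributions at `t`.
#' @export
calcium_kernel <- function(t, kinetics) {
  a <- kinetics$tau_rise; b <- kinetics$tau_decay
  tp <- a * log(1 + b / a)
  peak <- (1 - exp(-tp / a)) * exp(-tp / b)
  out <- ifelse(t >= 0, (1 - exp(-t / a)) * exp(-t / b) / peak, 0)
  kinetics$unitary_dff * out
}

#' Photodiode trace parameters
#'
#' Operating point of the photodiode channel: 60 Hz sampling, baseline
#' fluorescence photocurrent 19.7 nA, dark current 155 pA, and 1.5 pA
#' peak-to-peak instrument noise (Gaussian with SD = peak-to-peak / 6, the
#' +/- 3 sigma convention).
#'
#' @param sampling_rate Hz.
#' @param baseline_fluor Baseline fluorescence photocurrent (A).
#' @param dark_current Dark current (A).
#' @param noise_pp Peak-to-peak current noise (A).
#' @return A `photodiode_params` list.
#' @export
photodiode_params <- function(sampling_rate = 60, baseline_fluor = 19.7e-9,
                              dark_current = 155e-12, noise_pp = 1.5e-12) {
  stopifnot(sampling_rate > 0, baseline_fluor > 0, dark_current >= 0,
            noise_pp >= 0)
  structure(list(sampling_rate = sampling_rate,
                 baseline_fluor = baseline_fluor,
                 dark_current = dark_current, noise_pp = noise_pp),
            class = "photodiode_params")
}

#' Render the photodiode current trace
#'
#' Sums, over indicator-positive neurons only, the unitary calcium kernel at
#' each spike time, weighted per neuron by its detection probability (from a
#' supplied weight function of position, or 1), then converts the summed
#' dF/F(t) to current: `baseline_fluor * (1 + dFF) + dark_current` plus
#' Gaussian instrument noise, sampled at 60 Hz. Indicator-negative neurons
#' never touch the trace.
#'
#' @param trains From [generate_spike_trains()].
#' @param population The matching population.
#' @param kinetics A [calcium_kinetics()].
#' @param duration Trace duration (s); defaults to the trains' duration.
#' @param params A [photodiode_params()].
#' @param weight_fun Optional `function(x, y, z)` returning the per-neuron
#'   detection weight; default weight 1 for every indicator-positive neuron.
#' @param noise Logical; add instrument noise.
#' @param seed Noise seed.
#' @return A `photodiode_trace`: `current` (A), `sampling_rate`, `params`,
#'   and the ground-truth noiseless `dff_true`.
#' @export
render_calcium_current <- function(trains, population,
                                   kinetics = calcium_kinetics(),
                                   duration = NULL,
                                   params = photodiode_params(),
                                   weight_fun = NULL, noise = TRUE,
                                   seed = 1) {
  stopifnot(inherits(kinetics, "calcium_kinetics"),
            inherits(params, "photodiode_params"))
  duration <- duration %||% attr(trains, "duration")
  fs <- params$sampling_rate
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  dff <- numeric(n)
  support <- ceiling((kinetics$tau_decay * 8) * fs) # kernel tail cut at 8 tau
  for (i in seq_len(nrow(population))) {
    if (!population$indicator_positive[i]) next
    w <- if (is.null(weight_fun)) 1 else
      weight_fun(population$x[i], population$y[i], population$z[i])
    for (ts in trains[[as.character(population$id[i])]]) {
      i0 <- floor(ts * fs) + 1
      if (i0 > n) next
      idx <- i0:min(n, i0 + support)
      dff[idx] <- dff[idx] + w * calcium_kernel(t[idx] - ts, kinetics)
    }
  }
  current <- params$baseline_fluor * (1 + dff) + params$dark_current
  if (noise && params$noise_pp > 0)
    current <- current +
      with_seed(seed, rnorm(n, sd = params$noise_pp / 6))
  structure(list(current = current, sampling_rate = fs, params = params,
                 dff_true = dff),
            class = "photodiode_trace")
}

#' Biphasic extracellular spike template
#'
#' Canonical ~1 ms biphasic waveform (sharp negative phase followed by a
#' smaller positive after-phase), normalized to a negative peak of -1.
#'
#' @param fs Sampling rate (Hz).
#' @param window Template length (s); default 1.6 ms.
#' @return Numeric template vector.
#' @export
spike_template <- function(fs = 30000, window = 1.6e-3) {
  t <- seq(0, window, by = 1 / fs)
  w <- -exp(-((t - 0.35e-3) / 0.12e-3)^2) +
    0.35 * exp(-((t - 0.75e-3) / 0.30e-3)^2)
  w / abs(min(w))
}

#' Render the multichannel extracellular recording
#'
#' Adds, for every spike of every neuron, the spike template scaled on each
#' electrode by the bounded amplitude-decay law
#' `amplitude(d) = soma_amplitude * d0 / (d0 + d)` (d the soma-electrode
#' distance), plus per-channel Gaussian noise, at 30 kHz across the probe's
#' seven electrodes.
#'
#' @param trains,population As in [render_calcium_current()].
#' @param geometry A [probe_geometry()] supplying the electrode sites.
#' @param duration Recording duration (s).
#' @param fs Sampling rate (Hz), default 30000.
#' @param d0 Decay half-distance (um), default 20. The trilateration solver
#'   must invert the same law.
#' @param noise_sd Per-channel noise SD (uV).
#' @param template Spike waveform; default [spike_template()].
#' @param noise Logical; add channel noise.
#' @param seed Noise seed.
#' @return An `extracellular_recording`: `samples` (n x 7 matrix, uV),
#'   `sampling_rate`, `electrode_sites`, `d0`, `noise_sd`.
#' @export
render_extracellular <- function(trains, population, geometry,
                                 duration = NULL, fs = 30000, d0 = 20,
                                 noise_sd = 8, template = NULL,
                                 noise = TRUE, seed = 1) {
  stopifnot(inherits(geometry, "probe_geometry"))
  duration <- duration %||% attr(trains, "duration")
  if (is.null(template)) template <- spike_template(fs)
  sites <- geometry$electrode_sites
  nch <- nrow(sites)
  n <- floor(duration * fs)
  x <- matrix(0, n, nch)
  lt <- length(template)
  for (i in seq_len(nrow(population))) {
    pos <- c(population$x[i], population$y[i], population$z[i])
    d <- sqrt(rowSums((sites - matrix(pos, nch, 3, byrow = TRUE))^2))
    amps <- population$soma_amplitude[i] * d0 / (d0 + d)
    if (all(amps < noise_sd))
      warning(sprintf("neuron %d is below the noise floor on every channel",
                      population$id[i]))
    for (ts in trains[[as.character(population$id[i])]]) {
      i0 <- round(ts * fs) + 1
      if (i0 > n) next
      idx <- i0:min(n, i0 + lt - 1)
      seg <- template[seq_along(idx)]
      x[idx, ] <- x[idx, ] + outer(seg, amps)
    }
  }
  if (noise && noise_sd > 0)
    x <- x + with_seed(seed, matrix(rnorm(n * nch, sd = noise_sd), n, nch))
  structure(list(samples = x, sampling_rate = fs, electrode_sites = sites,
                 d0 = d0, noise_sd = noise_sd),
            class = "extracellular_recording")
}
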