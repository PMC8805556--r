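# Synthetic-data generator: determinism, configured rates, rendering laws.

test_that("population draws honour counts, fractions and determinism", {
  cfg <- synth_config()
  p1 <- generate_population(cfg, seed = 4)
  p2 <- generate_population(cfg, seed = 4)
  expect_identical(p1, p2)
  expect_equal(sum(p1$indicator_positive), 4) # round(6 * 4/6)
  expect_equal(nrow(p1), 6)
  box <- cfg$box
  expect_true(all(p1$x >= box[1, 1] & p1$x <= box[2, 1]))
  expect_true(all(p1$z >= box[1, 3] & p1$z <= box[2, 3]))

  p0 <- generate_population(synth_config(fraction_positive = 0), seed = 1)
  expect_false(any(p0$indicator_positive))

  expect_error(synth_config(n_neurons = 0))
  expect_error(synth_config(box = rbind(c(0, 0, 0), c(0, 0, 0))), "empty")
})

test_that("spike trains respect refractoriness and configured Poisson rates", {
  cfg <- synth_config(n_neurons = 3, fraction_positive = 1,
                      baseline_rate_range = c(4, 4), min_separation = 0)
  pop <- generate_population(cfg, seed = 2)
  pop$burst_rate <- 0
  tr <- generate_spike_trains(pop, duration = 200, seed = 2)
  for (ts in tr) {
    expect_true(all(diff(ts) >= 2e-3))
    # empirical rate within 3 SE of the configured 4 Hz (refractory loss
    # at 4 Hz x 2 ms is ~0.8%, inside the band)
    n <- length(ts)
    expect_lt(abs(n / 200 - 4), 3 * sqrt(4 / 200) + 0.04)
  }
  expect_identical(tr, generate_spike_trains(pop, duration = 200, seed = 2))
})

test_that("stimulation gain scales ON rates for connected neurons only", {
  sched <- stim_schedule(t_start = 0, t_end = 400)
  pop <- rbind(one_neuron(baseline_rate = 5),
               one_neuron(baseline_rate = 5))
  pop$id <- 1:2
  pop$opsin_connected <- c(TRUE, FALSE)
  tr <- generate_spike_trains(pop, schedule = sched, duration = 400,
                              stim_gain = 5, seed = 3)
  cyc <- stim_cycles(sched)
  rate_in <- function(ts, w) {
    tot <- sum(w[, 2] - w[, 1])
    sum(vapply(seq_len(nrow(w)), function(i)
      sum(ts >= w[i, 1] & ts < w[i, 2]), numeric(1))) / tot
  }
  on_w <- cbind(cyc$on_start, cyc$on_end)
  off_w <- cbind(cyc$on_end, cyc$off_end)
  r <- vapply(tr, function(ts)
    c(rate_in(ts, on_w), rate_in(ts, off_w)), numeric(2))
  # connected: ON/OFF ratio recovers the gain of 5
  ratio <- r[1, 1] / r[2, 1]
  expect_lt(abs(ratio - 5), 1)
  # non-connected: ON and OFF rates equal within 3 SE
  se <- sqrt(5 / sum(on_w[, 2] - on_w[, 1]) + 5 / sum(off_w[, 2] - off_w[, 1]))
  expect_lt(abs(r[1, 2] - r[2, 2]), 3 * se)
})

test_that("null stimulation leaves ON/OFF rates statistically equal", {
  sched <- stim_schedule(t_start = 0, t_end = 100)
  cfg1 <- synth_config(n_neurons = 1, fraction_positive = 1,
                       baseline_rate_range = c(5, 5), min_separation = 0)
  pop <- generate_population(cfg1, seed = 1)
  pop$burst_rate <- 0
  rej <- mean(vapply(1:120, function(s) {
    tr <- generate_spike_trains(pop, schedule = sched, duration = 100,
                                stim_gain = 1, seed = s)
    st <- stim_response(tr[[1]], sched, 100)
    st$p_on_off < 0.05
  }, logical(1)))
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("calcium kernel peaks at the closed-form time with unit amplitude", {
  kin <- calcium_kinetics(tau_rise = 0.05, tau_decay = 0.4,
                          unitary_dff = 0.02)
  tp <- kernel_peak_time(kin)
  expect_equal(tp, 0.05 * log(1 + 0.4 / 0.05))
  tg <- seq(0, 3, by = 1e-5)
  k <- calcium_kernel(tg, kin)
  expect_equal(max(k), kin$unitary_dff, tolerance = 1e-6)
  expect_equal(tg[which.max(k)], tp, tolerance = 1e-4)
  expect_equal(calcium_kernel(-0.1, kin), 0)
  expect_error(calcium_kinetics(tau_rise = 0.5, tau_decay = 0.4), "kinetics")
})

test_that("photodiode trace reproduces the probe operating point", {
  pop <- one_neuron()
  tr <- manual_trains(numeric(0), duration = 60)
  pd <- render_calcium_current(tr, pop, duration = 60, seed = 3)
  # no spikes: constant 19.7 nA + 155 pA plus noise
  n <- length(pd$current)
  se <- (photodiode_params()$noise_pp / 6) / sqrt(n)
  expect_lt(abs(mean(pd$current) - 19.855e-9), 3 * se)
  expect_equal(pd$sampling_rate, 60)

  # single spike, noise off: peak dF/F equals the closed-form kernel peak
  pd1 <- render_single_burst(1, t0 = 30, duration = 60)
  expect_equal(max(pd1$dff_true), calcium_kinetics()$unitary_dff,
               tolerance = 3e-3) # 60 Hz sampling of the flat peak

  # indicator-negative neuron firing hard leaves the trace bit-identical
  popn <- one_neuron(indicator_positive = FALSE)
  trn <- manual_trains(seq(0.5, 59.5, by = 0.01), duration = 60)
  pdn <- render_calcium_current(trn, popn, duration = 60, seed = 3)
  expect_identical(pdn$current, pd$current)
})

test_that("linear summation doubles with coincident spikes", {
  kin <- calcium_kinetics()
  for (n in c(2, 5)) {
    pop <- one_neuron()
    tr <- manual_trains(rep(30, n), duration = 60) # simultaneous spikes
    pd <- render_calcium_current(tr, pop, kin, duration = 60, noise = FALSE)
    one <- render_single_burst(1, t0 = 30, duration = 60)
    expect_equal(max(pd$dff_true), n * max(one$dff_true), tolerance = 1e-2)
  }
})

test_that("extracellular amplitudes follow the bounded decay law exactly", {
  geo <- probe_geometry()
  pos <- c(10, -20, 25)
  pop <- one_neuron(pos = pos, soma_amplitude = 240)
  tr <- manual_trains(0.05, duration = 0.2)
  rec <- render_extracellular(tr, pop, geo, duration = 0.2, noise = FALSE)
  amps <- -apply(rec$samples, 2, min)
  d <- sqrt(rowSums((geo$electrode_sites -
                       matrix(pos, 7, 3, byrow = TRUE))^2))
  expect_equal(amps, 240 * 20 / (20 + d), tolerance = 1e-9)

  # neuron exactly at an electrode site: that channel reads the soma
  # amplitude; a neuron equidistant from two sites drives them equally
  pop0 <- one_neuron(pos = geo$electrode_sites[2, ], soma_amplitude = 300)
  rec0 <- render_extracellular(manual_trains(0.05, 0.2), pop0, geo,
                               duration = 0.2, noise = FALSE)
  expect_equal(min(rec0$samples[, 2]), -300, tolerance = 1e-9)
  popm <- one_neuron(pos = c(0, 0, 30))
  recm <- render_extracellular(manual_trains(0.05, 0.2), popm, geo,
                               duration = 0.2, noise = FALSE)
  expect_equal(min(recm$samples[, 2]), min(recm$samples[, 5]),
               tolerance = 1e-12)

  # below the noise floor everywhere -> warning, still rendered
  popw <- one_neuron(pos = c(0, 0, 500), soma_amplitude = 100)
  expect_warning(render_extracellular(manual_trains(0.05, 0.2), popw, geo,
                                      duration = 0.2, noise_sd = 8,
                                      noise = FALSE),
                 "noise floor")
})
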