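# Fluorescence channel: dF/F, SNR, transient detection, kinetics, inference.

test_that("constant input yields an identically zero dF/F", {
  pd <- structure(list(current = rep(20e-9, 60 * 120), sampling_rate = 60,
                       params = photodiode_params()),
                  class = "photodiode_trace")
  dff <- compute_dff(pd, hp_cutoff = 0.1)
  expect_lt(max(abs(dff$values)), 1e-12)
  expect_true(all(dff$F0 > 0))
})

test_that("the 5 Hz second-order low-pass attenuates 10 Hz by 1/sqrt(17)", {
  # single-pass Butterworth magnitude, evaluated far from frequency warping
  fs <- 1000
  t <- (seq_len(40 * fs) - 1) / fs
  pd <- structure(list(current = 20e-9 * (1 + 0.01 * sin(2 * pi * 10 * t)),
                       sampling_rate = fs, params = photodiode_params()),
                  class = "photodiode_trace")
  dff1 <- suppressWarnings(compute_dff(pd, hp_cutoff = 0.05, lp_cutoff = 5,
                                       zero_phase = FALSE))
  mid <- 15000:25000
  gain <- max(dff1$values[mid]) / 0.01
  expect_equal(gain, 1 / sqrt(17), tolerance = 0.01)
  expect_equal(butter_gain(10, 5, 2, "low"), 1 / sqrt(17), tolerance = 1e-12)
  # zero-phase filtering applies the magnitude twice
  dff2 <- suppressWarnings(compute_dff(pd, hp_cutoff = 0.05, lp_cutoff = 5,
                                       zero_phase = TRUE))
  gain2 <- max(dff2$values[mid]) / 0.01
  expect_equal(gain2, 1 / 17, tolerance = 0.02)
})

test_that("a rendered transient survives the filter chain within 3%", {
  # a transient slow against the 5 Hz smoothing corner passes nearly
  # intact; the residual ~2.5% is baseline-high-pass sag, which is
  # inherent to a 0.05 Hz second-order baseline filter at this transient
  # duration (faster kinetics additionally lose peak to the low-pass)
  kin <- calcium_kinetics(tau_rise = 0.2, tau_decay = 1.5)
  pd <- render_single_burst(6, t0 = 150, duration = 300, kinetics = kin)
  dff <- compute_dff(pd, hp_cutoff = 0.05, lp_cutoff = 5)
  i0 <- 150 * 60
  resp <- max(dff$values[i0:(i0 + 240)]) - dff$values[i0]
  expect_equal(resp, max(pd$dff_true), tolerance = 0.03)
})

test_that("SNR is definitional and scale invariant", {
  base <- rep(c(-1, 1) * 1e-3, 300)
  v <- c(base, 9 * sd(base), base)
  dff <- as_dff(v)
  snr <- compute_snr(dff, baseline_window = seq_along(base))
  expect_equal(snr, 3)
  dff2 <- as_dff(5 * v)
  expect_equal(compute_snr(dff2, seq_along(base)), snr)
  expect_error(compute_snr(as_dff(rep(1, 100)), 1:50), "undefined SNR")
})

test_that("transient detection is calibrated on pure noise and exact on signal", {
  # false positives on iid Gaussian noise: a sample is a detection when it
  # is a strict local maximum above 3 sd; P ~ P(X > 3 sd) since at that
  # height both neighbours are below with near certainty
  set.seed(99)
  n <- 1e4
  counts <- vapply(1:40, function(s) {
    v <- rnorm(n)
    tr <- detect_transients(as_dff(v), k = 3, min_separation = 0,
                            noise_sd = 1)
    nrow(tr)
  }, numeric(1))
  expected <- n * (1 - pnorm(3))
  se <- sqrt(expected / 40) # Poisson-ish
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)

  # two rendered transients 2 s apart: exactly two detections at the truth
  kin <- calcium_kinetics()
  pop <- one_neuron()
  tr <- manual_trains(c(100, 102), duration = 200)
  pd <- render_calcium_current(tr, pop, kin, duration = 200, noise = FALSE)
  dff <- compute_dff(pd, hp_cutoff = 0.05, lp_cutoff = NULL)
  det <- detect_transients(dff, k = 3, noise_sd = 1e-3)
  expect_equal(nrow(det), 2)
  tp <- kernel_peak_time(kin)
  expect_lt(max(abs(det$peak_time - (c(100, 102) + tp))), 1 / 60 + 1e-9)
  expect_true(all(det$onset <= det$peak_time))

  # empty trace and monotonicity in the threshold
  expect_equal(nrow(detect_transients(as_dff(numeric(0)))), 0)
  v <- abs(rnorm(5000))
  ns <- vapply(c(1, 2, 3, 4), function(k)
    nrow(detect_transients(as_dff(v), k = k, min_separation = 0,
                           noise_sd = 1)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("rise and decay times match the closed forms of the kernel", {
  kin <- calcium_kinetics(tau_rise = 0.05, tau_decay = 0.4)
  # dense sampling so interpolation error is negligible
  fs <- 1000
  tg <- seq(0, 5, by = 1 / fs)
  v <- calcium_kernel(tg, kin)
  dff <- as_dff(v, fs = fs)
  tr <- list(peak_time = tg[which.max(v)])
  mk <- measure_kinetics(dff, tr)
  # independent oracle: invert the kernel numerically
  peak <- max(v)
  tp <- tg[which.max(v)]
  cross <- function(level, lower, upper)
    uniroot(function(t) calcium_kernel(t, kin) - level, c(lower, upper),
            tol = 1e-10)$root
  rise_ref <- cross(0.9 * peak, 0.5 * tp, tp) - cross(0.1 * peak, 1e-6, tp)
  decay_ref <- cross(peak / exp(1), tp, 5) - tp
  expect_equal(mk$rise_time, rise_ref, tolerance = 2 / fs)
  expect_equal(mk$decay_time, decay_ref, tolerance = 2 / fs)
  expect_false(mk$censored)

  # the same waveform at 60 Hz reads longer by at most one sample interval
  fs2 <- 60
  tg2 <- seq(0, 5, by = 1 / fs2)
  dff2 <- as_dff(calcium_kernel(tg2, kin), fs = fs2)
  mk2 <- measure_kinetics(dff2, list(peak_time =
                                       tg2[which.max(dff2$values)]))
  expect_lt(abs(mk2$rise_time - rise_ref), 1 / fs2 + 1e-9)

  # symmetric triangle: rise equals the mirrored decay-side interval
  tri <- c(seq(0, 1, length.out = 61), seq(1, 0, length.out = 61)[-1])
  dfft <- as_dff(tri, fs = 60)
  mkt <- measure_kinetics(dfft, list(peak_time = 1))
  expect_equal(mkt$rise_time, 0.8, tolerance = 1e-6)

  # peak at the segment edge is censored
  vshort <- calcium_kernel(seq(0, kernel_peak_time(kin), by = 1 / 60), kin)
  mkc <- measure_kinetics(as_dff(vshort), list(peak_time =
                                                 (length(vshort) - 1) / 60))
  expect_true(mkc$censored)
})

test_that("greedy deconvolution recovers burst spike counts", {
  kin <- calcium_kinetics()
  expect_error(infer_spike_counts(as_dff(rnorm(100)), kinetics = NULL),
               "kinetics")

  # flat trace: all-zero counts
  flat <- infer_spike_counts(as_dff(rep(0, 600)), kin)
  expect_true(all(flat$counts == 0))

  # one unitary transient, noise off: one spike in its bin, zero elsewhere
  pd <- render_single_burst(1, t0 = 100, duration = 200)
  dff <- compute_dff(pd, hp_cutoff = 0.05, lp_cutoff = NULL)
  inf <- infer_spike_counts(dff, kin, noise_sd = 1e-4)
  expect_equal(sum(inf$counts), 1)
  expect_equal(inf$counts[findInterval(100, inf$bin_starts)], 1L)

  # 4-spike burst within 200 ms at default instrument noise: 4 +/- 1 in
  # at least 90% of seeded replicates
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    t0 <- 100 + runif(1, 0, 0.1)
    tr <- manual_trains(cumsum(c(t0, runif(3, 5e-3, 10e-3))), 200)
    pd <- render_calcium_current(tr, one_neuron(), kin, duration = 200,
                                 noise = TRUE, seed = s)
    dffb <- compute_dff(pd, hp_cutoff = 0.05, lp_cutoff = 5)
    infb <- infer_spike_counts(dffb, kin)
    abs(infb$counts[findInterval(t0, infb$bin_starts)] - 4) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
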