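#' Band-pass filter an extracellular recording
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass, default
#' 0.3-6 kHz, applied per channel. DC is removed exactly (a band-pass has
#' zero gain at 0 Hz).
#'
#' @param recording An `extracellular_recording`.
#' @param low,high Band edges (Hz); `high` must stay below Nyquist.
#' @param order Filter order per edge, default 2.
#' @return The recording with filtered `samples`.
#' @export
bandpass_ephys <- function(recording, low = 300, high = 6000, order = 2) {
  fs <- recording$sampling_rate
  if (high >= fs / 2)
    stop("upper cutoff at or above Nyquist", call. = FALSE)
  stopifnot(low > 0, low < high)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- recording$samples
  # remove the channel mean first: the pass band excludes DC anyway, and a
  # zero-mean input avoids filter start-up transients at the trace edges
  for (j in seq_len(ncol(x)))
    x[, j] <- as.numeric(signal::filtfilt(bf, x[, j] - mean(x[, j])))
  recording$samples <- x
  recording$band <- c(low, high)
  recording
}

#' Detect spikes on one filtered channel
#'
#' Negative-threshold detection (extracellular convention): the channel
#' noise SD is estimated robustly as MAD / 0.6745, local minima below
#' `-k * SD` are events, and a refractory period suppresses later crossings.
#'
#' @param x Filtered channel samples (uV).
#' @param fs Sampling rate (Hz).
#' @param k Threshold multiplier, default 4.5.
#' @param refractory Dead time after each accepted event (s).
#' @return List with `times` (s), `indices`, `threshold`, `noise_sd`.
#' @export
detect_spikes <- function(x, fs, k = 4.5, refractory = 1e-3) {
  s <- mad(x) # stats::mad already scales by 1/0.6745
  th <- -k * s
  n <- length(x)
  out <- list(times = numeric(0), indices = integer(0), threshold = th,
              noise_sd = s)
  if (n < 3 || s == 0) return(out)
  ismin <- c(FALSE, x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] < x[3:n],
             FALSE) & x < th
  idx <- which(ismin)
  if (length(idx) == 0) return(out)
  dead <- round(refractory * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in idx) {
    if (i - last >= dead) { keep <- c(keep, i); last <- i }
  }
  out$times <- (keep - 1) / fs
  out$indices <- keep
  out
}

# Pool per-channel detections into distinct events: detections within
# `merge_window` of each other are one physical spike; the event time is the
# sample of the deepest trough among them.
pool_events <- function(det_list, x, fs, merge_window = 0.5e-3) {
  all_idx <- integer(0); all_ch <- integer(0)
  for (j in seq_along(det_list)) {
    all_idx <- c(all_idx, det_list[[j]]$indices)
    all_ch <- c(all_ch, rep(j, length(det_list[[j]]$indices)))
  }
  if (!length(all_idx)) return(integer(0))
  ord <- order(all_idx)
  all_idx <- all_idx[ord]; all_ch <- all_ch[ord]
  win <- round(merge_window * fs)
  groups <- cumsum(c(TRUE, diff(all_idx) > win))
  vapply(split(seq_along(all_idx), groups), function(ii) {
    depths <- vapply(ii, function(q) x[all_idx[q], all_ch[q]], numeric(1))
    all_idx[ii[which.min(depths)]]
  }, numeric(1))
}

#' Sort detected spikes into units
#'
#' Deterministic leader-follower clustering of events by their multichannel
#' peak-amplitude vectors: events are processed in time order; each event's
#' 7-channel amplitude vector (trough depth per channel around the event) is
#' compared by cosine distance to the running mean vector of each existing
#' unit, joining the nearest unit within `threshold` or founding a new one.
#' Overlapping spikes from distinct neurons may merge; this is a documented
#' limitation of the amplitude-vector approach.
#'
#' @param recording A band-pass-filtered `extracellular_recording`.
#' @param k Detection threshold multiplier (see [detect_spikes()]).
#' @param threshold Cosine-distance linkage tolerance, default 0.02.
#' @param waveform_window Waveform extraction window (s), default 1.6 ms.
#' @param refractory Per-channel detection dead time (s).
#' @param min_spikes Units with fewer events are dropped (isolated
#'   threshold crossings of the noise floor form tiny spurious clusters);
#'   set to 1 to keep everything.
#' @return List of `sorted_unit` objects, ordered by first appearance; each
#'   has `id`, `timestamps` (s), `mean_waveform` (window x channels),
#'   `per_channel_amplitude` (uV, >= 0), `primary_channel`, `snr`,
#'   `n_spikes`, `noise_sd`.
#' @export
sort_units <- function(recording, k = 4.5, threshold = 0.02,
                       waveform_window = 1.6e-3, refractory = 1e-3,
                       min_spikes = 5) {
  x <- recording$samples
  fs <- recording$sampling_rate
  nch <- ncol(x)
  det <- lapply(seq_len(nch), function(j)
    detect_spikes(x[, j], fs, k = k, refractory = refractory))
  noise_sd <- vapply(det, function(d) d$noise_sd, numeric(1))
  ev <- pool_events(det, x, fs)
  if (!length(ev)) return(list())
  half <- round(waveform_window * fs / 2)
  # trough depth per channel in a narrow (+/- 2 sample) window about the
  # event trough: wider windows let the noise floor minima inflate weak
  # channels and blur the vectors
  amp_at <- function(i) {
    idx <- max(1, i - 2):min(nrow(x), i + 2)
    pmax(0, -apply(x[idx, , drop = FALSE], 2, min))
  }
  leaders <- list()   # running mean amplitude vectors
  counts <- integer(0)
  assign_id <- integer(length(ev))
  for (e in seq_along(ev)) {
    a <- amp_at(ev[e])
    if (sum(a) == 0) { assign_id[e] <- NA_integer_; next }
    an <- a / sqrt(sum(a^2))
    best <- NA_integer_; bestd <- Inf
    for (u in seq_along(leaders)) {
      l <- leaders[[u]]
      d <- 1 - sum(an * l / sqrt(sum(l^2)))
      if (d < bestd) { bestd <- d; best <- u }
    }
    if (is.finite(bestd) && bestd < threshold) {
      leaders[[best]] <- (leaders[[best]] * counts[best] + an) /
        (counts[best] + 1)
      counts[best] <- counts[best] + 1
      assign_id[e] <- best
    } else {
      leaders[[length(leaders) + 1]] <- an
      counts <- c(counts, 1L)
      assign_id[e] <- length(leaders)
    }
  }
  sizes <- vapply(seq_along(leaders), function(u)
    sum(assign_id == u, na.rm = TRUE), numeric(1))
  kept <- which(sizes >= min_spikes)
  lapply(seq_along(kept), function(uu) {
    u <- kept[uu]
    ei <- ev[which(assign_id == u)]
    wf <- array(0, c(2 * half + 1, nch))
    m <- 0
    for (i in ei) {
      lo <- i - half; hi <- i + half
      if (lo < 1 || hi > nrow(x)) next
      wf <- wf + x[lo:hi, , drop = FALSE]
      m <- m + 1
    }
    if (m > 0) wf <- wf / m
    amp <- pmax(0, -apply(wf, 2, min))
    pc <- which.max(amp)
    structure(list(id = uu, timestamps = (ei - 1) / fs,
                   mean_waveform = wf, per_channel_amplitude = amp,
                   primary_channel = pc,
                   snr = if (noise_sd[pc] > 0) amp[pc] / (3 * noise_sd[pc])
                         else NA_real_,
                   n_spikes = length(ei), noise_sd = noise_sd),
              class = "sorted_unit")
  })
}

#' @export
print.sorted_unit <- function(x, ...) {
  cat(sprintf("<sorted_unit %d> %d spikes, primary ch %d, SNR %.2f\n",
              x$id, x$n_spikes, x$primary_channel, x$snr))
  invisible(x)
}

#' Unit signal-to-noise ratio
#'
#' `SNR = max(|peak|) / (3 * SD)` of the unit's mean waveform on its primary
#' channel against that channel's robust noise SD.
#'
#' @param unit A `sorted_unit`.
#' @param recording Optional filtered recording for a fresh noise estimate;
#'   default reuses the noise SD captured at sorting time.
#' @return SNR scalar.
#' @export
unit_snr <- function(unit, recording = NULL) {
  s <- if (is.null(recording)) unit$noise_sd[unit$primary_channel]
       else mad(recording$samples[, unit$primary_channel])
  if (!is.finite(s) || s == 0)
    stop("undefined SNR: noise SD is zero", call. = FALSE)
  unit$per_channel_amplitude[unit$primary_channel] / (3 * s)
}

#' Trilaterate a unit position from its amplitude vector
#'
#' Inverts the amplitude-decay law `A_i = A0 * d0 / (d0 + d_i)` jointly over
#' the soma amplitude A0 and the 3D position: nonlinear least squares on the
#' per-channel amplitudes with the electrode coordinates as known centres,
#' depth constrained to the tissue side (z >= 0). With fewer than 3 channels
#' above the noise floor the estimate falls back to the amplitude-weighted
#' electrode centroid and is flagged.
#'
#' @param unit A `sorted_unit` (or list with `per_channel_amplitude`).
#' @param geometry A [probe_geometry()].
#' @param d0 Decay half-distance (um); must match the law that generated the
#'   amplitudes.
#' @param noise_floor Minimum usable amplitude (uV); default `3 * noise SD`
#'   of each channel when available, else 0.
#' @return A `unit_position`: `estimate` (xyz, um), `residual` (RMS amplitude
#'   misfit, uV), `n_channels_used`, `fallback` flag.
#' @export
trilaterate <- function(unit, geometry, d0 = 20, noise_floor = NULL) {
  a <- unit$per_channel_amplitude
  sites <- geometry$electrode_sites
  if (is.null(noise_floor))
    noise_floor <- if (!is.null(unit$noise_sd)) 3 * unit$noise_sd else 0
  usable <- which(a > noise_floor)
  if (length(usable) == 0)
    stop("unlocatable unit: all amplitudes at the noise floor", call. = FALSE)
  if (length(usable) < 3) {
    w <- a[usable] / sum(a[usable])
    est <- colSums(sites[usable, , drop = FALSE] * w)
    return(structure(list(estimate = est, residual = NA_real_,
                          n_channels_used = length(usable), fallback = TRUE),
                     class = "unit_position"))
  }
  s <- sites[usable, , drop = FALSE]
  av <- a[usable]
  obj <- function(p) {
    d <- sqrt(rowSums((s - matrix(p[1:3], nrow(s), 3, byrow = TRUE))^2))
    sum((av - p[4] * d0 / (d0 + d))^2)
  }
  w0 <- av / sum(av)
  c0 <- colSums(s * w0)
  fits <- lapply(c(10, 30, 60), function(z0) {
    start <- c(c0[1], c0[2], z0, max(av) * (d0 + z0) / d0)
    optim(start, obj, method = "L-BFGS-B",
          lower = c(-Inf, -Inf, 0, 1e-6),
          control = list(maxit = 500, factr = 1e4))
  })
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  structure(list(estimate = best$par[1:3],
                 soma_amplitude = best$par[4],
                 residual = sqrt(best$value / length(av)),
                 n_channels_used = length(usable), fallback = FALSE),
            class = "unit_position")
}

#' @export
print.unit_position <- function(x, ...) {
  cat(sprintf("<unit_position> (%.1f, %.1f, %.1f) um, residual %.3g, %d channels%s\n",
              x$estimate[1], x$estimate[2], x$estimate[3], x$residual,
              x$n_channels_used, if (x$fallback) " [centroid fallback]" else ""))
  invisible(x)
}
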