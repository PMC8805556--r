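#' Single-pass Butterworth magnitude response
#'
#' Closed-form magnitude `1 / sqrt(1 + (f/fc)^(2n))` of an order-`n` low-pass
#' Butterworth at frequency `f` (high-pass: invert the ratio). Zero-phase
#' forward-backward filtering applies this magnitude twice.
#'
#' @param f Frequency (Hz).
#' @param cutoff Cutoff frequency (Hz).
#' @param order Filter order.
#' @param type `"low"` or `"high"`.
#' @return Magnitude gain in (0, 1].
#' @export
butter_gain <- function(f, cutoff, order = 2, type = c("low", "high")) {
  type <- match.arg(type)
  r <- if (type == "low") f / cutoff else cutoff / f
  1 / sqrt(1 + r^(2 * order))
}

apply_butter <- function(x, cutoff, fs, type, order = 2, zero_phase = TRUE) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  if (zero_phase) as.numeric(signal::filtfilt(bf, x))
  else as.numeric(signal::filter(bf, x))
}

#' Compute dF/F from a photodiode trace
#'
#' Baseline correction and normalization of the 60 Hz fluorescence channel:
#' the dark current is subtracted, a second-order Butterworth high-pass
#' (cutoff in 0.05-0.1 Hz) extracts the fast component F(t) - F0(t) while
#' the per-sample slow baseline F0(t) is the complement `raw - highpass`;
#' dF/F = (F - F0)/F0 per sample; finally a second-order 5 Hz Butterworth
#' low-pass attenuates residual noise. Filtering is zero-phase
#' (forward-backward) by default so transient onset times are unbiased; set
#' `zero_phase = FALSE` for a causal single pass with the textbook
#' Butterworth magnitude (see [butter_gain()]).
#'
#' @param trace A `photodiode_trace` (or list with `current` and
#'   `sampling_rate`).
#' @param hp_cutoff Baseline high-pass cutoff (Hz), default 0.05.
#' @param lp_cutoff Smoothing low-pass cutoff (Hz), default 5; `NULL` skips.
#' @param zero_phase Logical, default TRUE.
#' @param subtract_dark Subtract the dark current before normalization.
#' @return A `dff_trace`: `values`, `sampling_rate`, `F0` (per-sample
#'   baseline), `filter_settings`.
#' @export
compute_dff <- function(trace, hp_cutoff = 0.05, lp_cutoff = 5,
                        zero_phase = TRUE, subtract_dark = TRUE) {
  x <- trace$current
  fs <- trace$sampling_rate
  period <- 1 / hp_cutoff
  if (length(x) / fs < period)
    stop("trace shorter than one high-pass period", call. = FALSE)
  if (length(x) / fs < 10 * period)
    warning("trace shorter than 10 high-pass periods; baseline estimate may be poor")
  if (subtract_dark && !is.null(trace$params))
    x <- x - trace$params$dark_current
  # centre before filtering: the filter state is initialized around zero, so
  # filtering the raw ~nA-offset trace directly would ring at both edges
  hp <- apply_butter(x - mean(x), hp_cutoff, fs, "high",
                     zero_phase = zero_phase)
  f0 <- x - hp
  if (any(f0 <= 0))
    stop("degenerate input: non-positive baseline after dark subtraction",
         call. = FALSE)
  dff <- hp / f0
  if (!is.null(lp_cutoff))
    dff <- apply_butter(dff, lp_cutoff, fs, "low", zero_phase = zero_phase)
  structure(list(values = dff, sampling_rate = fs, F0 = f0,
                 filter_settings = list(hp_cutoff = hp_cutoff,
                                        lp_cutoff = lp_cutoff, order = 2,
                                        zero_phase = zero_phase)),
            class = "dff_trace")
}

baseline_sd <- function(dff, baseline_window = NULL) {
  v <- dff$values
  if (!is.null(baseline_window)) v <- v[baseline_window]
  sd(v)
}

#' Signal-to-noise ratio of a dF/F trace
#'
#' `SNR = max(peak) / (3 * SD)` with the SD taken over a transient-free
#' baseline window.
#'
#' @param dff A `dff_trace`.
#' @param baseline_window Integer sample indices of a transient-free stretch.
#' @return SNR scalar.
#' @export
compute_snr <- function(dff, baseline_window) {
  s <- baseline_sd(dff, baseline_window)
  if (!is.finite(s) || s == 0)
    stop("undefined SNR: baseline SD is zero", call. = FALSE)
  max(dff$values) / (3 * s)
}

#' Detect calcium transients
#'
#' Local maxima of the dF/F trace exceeding `k` times a robust baseline SD
#' (median absolute deviation based), separated by at least
#' `min_separation`; the onset of each transient is the last crossing of 10%
#' of its peak before the peak.
#'
#' @param dff A `dff_trace`.
#' @param k Threshold multiplier, default 3.
#' @param min_separation Minimum peak separation (s).
#' @param noise_sd Optional externally supplied baseline SD; default is the
#'   MAD-based robust SD of the whole trace.
#' @param edge_exclusion Ignore peaks within this many seconds of either
#'   trace edge (residual filter edge effects), default 0.
#' @return Data frame (class `calcium_transients`) with `onset`,
#'   `peak_time`, `peak_dff` per transient, sorted by time; zero rows when
#'   nothing crosses threshold.
#' @export
detect_transients <- function(dff, k = 3, min_separation = 0.5,
                              noise_sd = NULL, edge_exclusion = 0) {
  v <- dff$values
  fs <- dff$sampling_rate
  s <- noise_sd %||% mad(v)
  empty <- data.frame(onset = numeric(0), peak_time = numeric(0),
                      peak_dff = numeric(0))
  class(empty) <- c("calcium_transients", "data.frame")
  if (length(v) < 3 || s == 0) return(empty)
  th <- k * s
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
                 v[2:(n - 1)] > v[3:n], FALSE) & v > th
  idx <- which(is_peak)
  if (edge_exclusion > 0) {
    m <- edge_exclusion * fs
    idx <- idx[idx > m & idx <= n - m]
  }
  if (length(idx) == 0) return(empty)
  # enforce separation, keeping the larger peak
  ord <- idx[order(v[idx], decreasing = TRUE)]
  keep <- logical(0)
  for (i in ord)
    if (all(abs(i - keep) >= min_separation * fs)) keep <- c(keep, i)
  keep <- sort(keep)
  onset <- vapply(keep, function(i) {
    below <- which(v[seq_len(i)] < 0.1 * v[i])
    j <- if (length(below)) max(below) else 1
    (j - 1) / fs
  }, numeric(1))
  out <- data.frame(onset = onset, peak_time = (keep - 1) / fs,
                    peak_dff = v[keep])
  class(out) <- c("calcium_transients", "data.frame")
  out
}

#' Measure transient kinetics
#'
#' Rise time as the 10%-to-90%-of-peak crossing interval before the peak and
#' decay time as the peak-to-1/e-of-peak interval after it, both with linear
#' interpolation between samples. A transient whose peak touches the segment
#' edge is flagged as censored.
#'
#' @param dff A `dff_trace`.
#' @param transient One row of [detect_transients()] output (or a list with
#'   `peak_time`).
#' @param segment Optional sample range to restrict the search.
#' @return List with `rise_time`, `decay_time` (s; `NA` when censored) and
#'   `censored` flag.
#' @export
measure_kinetics <- function(dff, transient, segment = NULL) {
  v <- dff$values
  if (!is.null(segment)) v <- v[segment]
  fs <- dff$sampling_rate
  ip <- round(transient$peak_time * fs) + 1 - (if (is.null(segment)) 0 else segment[1] - 1)
  n <- length(v)
  if (ip <= 1 || ip >= n)
    return(list(rise_time = NA_real_, decay_time = NA_real_, censored = TRUE))
  peak <- v[ip]

  cross_before <- function(level) {
    below <- which(v[seq_len(ip)] <= level)
    if (!length(below)) return(NA_real_)
    j <- max(below)
    if (j == ip) return((j - 1) / fs)
    # linear interpolation between samples j and j+1
    frac <- (level - v[j]) / (v[j + 1] - v[j])
    (j - 1 + frac) / fs
  }
  cross_after <- function(level) {
    below <- which(v[ip:n] <= level)
    if (!length(below)) return(NA_real_)
    j <- ip + min(below) - 1
    if (j == ip) return((j - 1) / fs)
    frac <- (v[j - 1] - level) / (v[j - 1] - v[j])
    (j - 2 + frac) / fs
  }
  t10 <- cross_before(0.1 * peak)
  t90 <- cross_before(0.9 * peak)
  te <- cross_after(peak / exp(1))
  censored <- is.na(te)
  list(rise_time = t90 - t10,
       decay_time = if (censored) NA_real_ else te - (ip - 1) / fs,
       censored = censored)
}

#' Infer spike counts by greedy template deconvolution
#'
#' Simplified spike inference: while the residual trace has a peak exceeding
#' the detection threshold (`k` times the noise SD), subtract the unitary
#' calcium kernel at the residual-maximizing sample and record one spike
#' there. Counts are reported per time bin (default 200 ms, the window used
#' to relate spike counts to calcium changes).
#'
#' @param dff A `dff_trace`.
#' @param kinetics A [calcium_kinetics()]; required.
#' @param bin Bin width (s), default 0.2.
#' @param k Threshold multiplier on the noise SD.
#' @param noise_sd Optional noise SD; default MAD-based estimate.
#' @param max_iter Iteration cap.
#' @return List with `counts` (per-bin spike counts), `bin_starts` (s),
#'   `spike_times` (s).
#' @export
infer_spike_counts <- function(dff, kinetics, bin = 0.2, k = 3,
                               noise_sd = NULL, max_iter = 10000) {
  if (missing(kinetics) || !inherits(kinetics, "calcium_kinetics"))
    stop("kinetics must be supplied as a calcium_kinetics object",
         call. = FALSE)
  v <- dff$values
  fs <- dff$sampling_rate
  s <- noise_sd %||% mad(v)
  th <- max(k * s, 0.25 * kinetics$unitary_dff)
  n <- length(v)
  support <- min(n, ceiling(kinetics$tau_decay * 8 * fs))
  tker <- (seq_len(support) - 1) / fs
  ker <- calcium_kernel(tker, kinetics)
  res <- v
  spikes <- numeric(0)
  for (it in seq_len(max_iter)) {
    i <- which.max(res)
    if (res[i] <= th) break
    # place the spike so the kernel peak aligns with the residual peak
    ipk <- which.max(ker)
    i0 <- max(1, i - ipk + 1)
    idx <- i0:min(n, i0 + support - 1)
    res[idx] <- res[idx] - ker[seq_along(idx)]
    spikes <- c(spikes, (i0 - 1) / fs)
  }
  spikes <- sort(spikes)
  edges <- seq(0, n / fs + bin, by = bin)
  counts <- as.integer(
    table(factor(findInterval(spikes, edges), levels = seq_len(length(edges) - 1))))
  list(counts = counts, bin_starts = edges[-length(edges)],
       spike_times = spikes)
}
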