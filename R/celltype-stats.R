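# Peak attenuation of an isolated unitary transient under the dF/F filter
# chain (baseline high-pass and optional low-pass) at the trace's sampling
# rate, relative to the configured unitary amplitude. Used to undo the
# known, deterministic filter loss when regressing calcium change on spike
# count.
unitary_attenuation <- function(kinetics, fset, fs) {
  pad <- ceiling(2 / fset$hp_cutoff * fs)
  tail_n <- ceiling(10 * kinetics$tau_decay * fs)
  x <- c(numeric(pad), calcium_kernel((seq_len(tail_n) - 1) / fs, kinetics),
         numeric(pad))
  y <- apply_butter(x - mean(x), fset$hp_cutoff, fs, "high",
                    order = fset$order, zero_phase = fset$zero_phase)
  if (!is.null(fset$lp_cutoff))
    y <- apply_butter(y, fset$lp_cutoff, fs, "low", order = fset$order,
                      zero_phase = fset$zero_phase)
  # measure exactly as the per-bin response does: peak minus the pre-onset
  # level (which carries the filter's anticipatory undershoot), averaged
  # over the possible onset positions inside a bin
  base <- mean(y[max(1, pad - 11):(pad + 1)])
  (max(y) - base) / kinetics$unitary_dff
}

# Classic pooled-variance two-sample two-tailed t-test with explicit
# handling of degenerate (zero-variance) inputs: identical groups give
# t = 0, p = 1; separated constant groups give |t| = Inf, p = 0.
pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_))
  m1 <- mean(x); m2 <- mean(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- if (se == 0) { if (m1 == m2) 0 else sign(m1 - m2) * Inf }
        else (m1 - m2) / se
  p <- if (is.infinite(tt)) 0 else 2 * pt(-abs(tt), n1 + n2 - 2)
  list(t = tt, p = p, df = n1 + n2 - 2)
}

# Deterministic placement of matched-duration rest windows inside the free
# (transient-excluded) part of the recording: walk the free intervals in
# time order, carving one window per requested duration with a small gap.
place_rest_windows <- function(durations, exclusions, duration, gap = 0.1) {
  free <- data.frame(start = 0, end = duration)
  if (nrow(exclusions)) {
    ex <- exclusions[order(exclusions$start), , drop = FALSE]
    pts <- c(0, as.vector(t(as.matrix(ex[, c("start", "end")]))), duration)
    starts <- pts[seq(1, length(pts) - 1, by = 2)]
    ends <- pts[seq(2, length(pts), by = 2)]
    free <- data.frame(start = pmin(pmax(starts, 0), duration),
                       end = pmin(pmax(ends, 0), duration))
    free <- free[free$end - free$start > 0, , drop = FALSE]
  }
  out <- data.frame(start = numeric(0), end = numeric(0))
  fi <- 1; cursor <- if (nrow(free)) free$start[1] else duration
  for (d in durations) {
    placed <- FALSE
    while (fi <= nrow(free)) {
      if (cursor + d <= free$end[fi]) {
        out <- rbind(out, data.frame(start = cursor, end = cursor + d))
        cursor <- cursor + d + gap
        placed <- TRUE
        break
      }
      fi <- fi + 1
      if (fi <= nrow(free)) cursor <- free$start[fi]
    }
    if (!placed) break
  }
  out
}

rate_in_windows <- function(spike_times, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sum(spike_times >= w$start & spike_times < w$end) / (w$end - w$start)
  }, numeric(1))
}

#' Firing rate during calcium rise versus rest
#'
#' Compares a unit's firing rate inside the rising phase of each detected
#' calcium transient (onset to peak) against matched-duration rest windows
#' placed deterministically in transient-free stretches of the recording
#' (each transient excluded out to twice the decay time past its peak), with
#' a classic two-sample two-tailed unpaired t-test on the per-window rates.
#'
#' @param spike_times Unit spike times (s).
#' @param transients [detect_transients()] output.
#' @param duration Recording duration (s).
#' @param decay_time Transient decay scale used for the exclusion zone (s).
#' @param min_windows Minimum usable rise windows; below it the result is
#'   flagged as insufficient evidence.
#' @return A `rise_rest_result`: `rate_rise`, `rate_rest` (Hz),
#'   `t_statistic`, `p_value`, `n_rise`, `n_rest`, `n_spikes_rise` (spikes
#'   inside rise windows), `insufficient` flag.
#' @export
rise_rest_rates <- function(spike_times, transients, duration,
                            decay_time = 0.4, min_windows = 3) {
  rise <- data.frame(start = transients$onset, end = transients$peak_time)
  rise <- rise[rise$end - rise$start > 0, , drop = FALSE]
  excl <- data.frame(start = transients$onset - 0.2,
                     end = transients$peak_time + 2 * decay_time)
  if (nrow(rise) < min_windows) {
    return(structure(list(rate_rise = NA_real_, rate_rest = NA_real_,
                          t_statistic = NA_real_, p_value = NA_real_,
                          n_rise = nrow(rise), n_rest = 0,
                          n_spikes_rise = 0, n_spikes_transient = 0,
                          insufficient = TRUE),
                     class = "rise_rest_result"))
  }
  rest <- place_rest_windows(rise$end - rise$start, excl, duration)
  r_rise <- rate_in_windows(spike_times, rise)
  r_rest <- rate_in_windows(spike_times, rest)
  tt <- pooled_t_test(r_rise, r_rest)
  structure(list(rate_rise = mean(r_rise), rate_rest = mean(r_rest),
                 t_statistic = tt$t, p_value = tt$p,
                 n_rise = nrow(rise), n_rest = nrow(rest),
                 n_spikes_rise = sum(vapply(seq_len(nrow(rise)), function(i)
                   sum(spike_times >= rise$start[i] &
                         spike_times < rise$end[i]), numeric(1))),
                 n_spikes_transient =
                   sum(vapply(seq_len(nrow(transients)), function(i)
                     sum(spike_times >= transients$onset[i] &
                           spike_times < transients$peak_time[i] +
                             2 * decay_time), numeric(1))),
                 insufficient = nrow(rest) < min_windows),
            class = "rise_rest_result")
}

#' Regress calcium change on spike count per bin
#'
#' Tiles the recording into bins (default 200 ms), counts the unit's spikes
#' per bin, measures the calcium change attributable to each bin as the rise
#' of the dF/F trace from the bin start to its maximum within the bin plus a
#' kernel-rise lookahead, and fits ordinary least squares of change on
#' count. By default only bins containing spikes enter the fit.
#'
#' @param spike_times Unit spike times (s).
#' @param dff A `dff_trace`.
#' @param bin Bin width (s), default 0.2.
#' @param lookahead Extra time past the bin end in which the evoked peak may
#'   fall (s); default 0.15, roughly the unitary kernel's time to peak.
#' @param min_count Minimum spikes for a bin to enter the fit.
#' @param kinetics Optional [calcium_kinetics()]. When supplied, each bin's
#'   response is divided by the kernel-timing attenuation factor (the peak
#'   of the kernels summed at the bin's actual spike offsets, relative to
#'   simultaneous spikes), so the slope estimates the unitary amplitude
#'   without the small downward bias that within-burst spike spacing
#'   introduces.
#' @param exclude_contaminated Drop bins whose measured peak could include
#'   another bin's calcium change (a spike inside the lookahead past the bin
#'   end, or a burst split across the bin start).
#' @return A `linear_fit`: `slope`, `intercept`, `r_squared`, `n_points`,
#'   `rank_deficient` flag, and the underlying `lm` as `model`.
#' @export
regression_spikes_dff <- function(spike_times, dff, bin = 0.2,
                                  lookahead = 0.15, min_count = 1,
                                  kinetics = NULL,
                                  exclude_contaminated = TRUE) {
  v <- dff$values
  fs <- dff$sampling_rate
  duration <- length(v) / fs
  edges <- seq(0, duration, by = bin)
  if (length(edges) < 2)
    stop("trace shorter than one bin", call. = FALSE)
  n_bins <- length(edges) - 1
  counts <- tabulate(findInterval(spike_times, edges,
                                  rightmost.closed = FALSE), n_bins)
  atten <- 1
  if (!is.null(kinetics) && !is.null(dff$filter_settings)) {
    atten <- unitary_attenuation(kinetics, dff$filter_settings, fs)
  }
  # per-sample renormalization: dF/F against the local (activity-inflated)
  # baseline understates the change relative to the quiet-period baseline
  f0_ratio <- if (!is.null(kinetics) && !is.null(dff$F0)) {
    dff$F0 / unname(quantile(dff$F0, 0.05))
  } else rep(1, length(v))
  resp <- vapply(seq_len(n_bins), function(b) {
    i0 <- floor(edges[b] * fs) + 1
    i1 <- min(length(v), floor((edges[b + 1] + lookahead) * fs))
    imax <- i0 + which.max(v[i0:i1]) - 1
    base <- v[i0]
    if (!is.null(kinetics) && base > 0) {
      # a decaying tail of earlier calcium does not persist at its bin-start
      # level: project it forward to the peak with the decay constant
      base <- base * exp(-((imax - i0) / fs) / kinetics$tau_decay)
    }
    r <- (v[imax] - base) * f0_ratio[imax]
    if (!is.null(kinetics)) {
      st <- spike_times[spike_times >= edges[b] & spike_times < edges[b + 1]]
      if (length(st) > 1) {
        off <- st - st[1]
        tg <- seq(0, max(off) + 2 * kinetics$tau_rise *
                    log(1 + kinetics$tau_decay / kinetics$tau_rise),
                  by = 1e-3)
        pk <- max(Reduce(`+`, lapply(off, function(o)
          calcium_kernel(tg - o, kinetics))))
        r <- r * length(st) * kinetics$unitary_dff / pk
      }
    }
    r / atten
  }, numeric(1))
  use <- counts >= min_count
  if (isTRUE(exclude_contaminated)) {
    clean <- vapply(seq_len(n_bins), function(b) {
      # a burst split across the bin boundary (or one starting inside the
      # lookahead) would credit this bin with another bin's calcium change
      !any(spike_times > edges[b + 1] &
             spike_times <= edges[b + 1] + lookahead) &&
        !any(spike_times > edges[b] - lookahead - 0.1 &
               spike_times <= edges[b])
    }, logical(1))
    use <- use & clean
  }
  x <- counts[use]; y <- resp[use]
  rank_deficient <- length(unique(x)) < 3
  if (length(unique(x)) < 2) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_points = sum(use),
                          rank_deficient = TRUE, model = NULL),
                     class = "linear_fit"))
  }
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_points = sum(use),
                 rank_deficient = rank_deficient,
                 model = fit),
            class = "linear_fit")
}

#' Stimulation-response firing statistics
#'
#' Per-cycle firing rates during the ON and OFF phases of a periodic optical
#' stimulation schedule, plus control rates from matched-length segments of
#' the pre-stimulation period, with classic two-tailed unpaired t-tests
#' ON-vs-OFF and OFF-vs-control.
#'
#' @param spike_times Unit spike times (s).
#' @param schedule A [stim_schedule()].
#' @param duration Recording duration (s); cycles must fit inside it.
#' @param min_cycles Minimum stimulation cycles, default 5.
#' @return A `stim_response_result`: `rate_on`, `rate_off`, `rate_control`
#'   (Hz), `p_on_off`, `p_off_control`, `n_cycles`.
#' @export
stim_response <- function(spike_times, schedule, duration,
                          min_cycles = 5) {
  cyc <- stim_cycles(schedule)
  cyc <- cyc[cyc$off_end <= duration + 1e-9, , drop = FALSE]
  if (nrow(cyc) < min_cycles)
    stop(sprintf("schedule provides %d cycle(s) inside the recording; need >= %d",
                 nrow(cyc), min_cycles), call. = FALSE)
  on_w <- data.frame(start = cyc$on_start, end = cyc$on_end)
  off_w <- data.frame(start = cyc$on_end, end = cyc$off_end)
  r_on <- rate_in_windows(spike_times, on_w)
  r_off <- rate_in_windows(spike_times, off_w)
  # control: tile the pre-stimulation span with OFF-length segments
  off_len <- off_w$end[1] - off_w$start[1]
  pre <- schedule$t_start
  n_ctl <- floor(pre / off_len)
  r_ctl <- if (n_ctl >= 2) {
    ctl_w <- data.frame(start = (seq_len(n_ctl) - 1) * off_len)
    ctl_w$end <- ctl_w$start + off_len
    rate_in_windows(spike_times, ctl_w)
  } else numeric(0)
  structure(list(rate_on = mean(r_on), rate_off = mean(r_off),
                 rate_control = if (length(r_ctl)) mean(r_ctl) else NA_real_,
                 p_on_off = pooled_t_test(r_on, r_off)$p,
                 p_off_control = if (length(r_ctl) >= 2)
                   pooled_t_test(r_off, r_ctl)$p else NA_real_,
                 n_cycles = nrow(cyc)),
            class = "stim_response_result")
}

#' Classify a unit as indicator-positive or -negative
#'
#' Decision rule operationalizing "strong correlation between electrical and
#' fluorescence signals": a unit is `indicator_positive` when its rise/rest
#' t-test is significant at `alpha` with a higher rate during calcium rises;
#' a unit that fails that criterion but fired at least `min_spikes` times
#' inside transient windows (onset to twice the decay time past the peak) is
#' `indicator_negative` - it fired, but calcium did not follow; a unit that
#' was essentially silent during the transients is `unclassified`.
#'
#' @param rise_rest A `rise_rest_result`.
#' @param fit Optional `linear_fit` evidence.
#' @param stim Optional `stim_response_result` evidence.
#' @param alpha Significance level, default 0.05.
#' @param min_spikes Minimum spikes inside transient windows for a confident
#'   negative call.
#' @return A `cell_type_call`: `label` in
#'   `c("indicator_positive", "indicator_negative", "unclassified")` plus
#'   the evidence objects.
#' @export
classify_cell_type <- function(rise_rest, fit = NULL, stim = NULL,
                               alpha = 0.05, min_spikes = 2) {
  label <- "unclassified"
  if (!isTRUE(rise_rest$insufficient) && is.finite(rise_rest$p_value)) {
    if (rise_rest$p_value < alpha && rise_rest$rate_rise > rise_rest$rate_rest)
      label <- "indicator_positive"
    else if (rise_rest$n_spikes_transient >= min_spikes)
      label <- "indicator_negative"
  }
  structure(list(label = label, rise_rest = rise_rest, fit = fit,
                 stim = stim, alpha = alpha),
            class = "cell_type_call")
}

#' @export
print.cell_type_call <- function(x, ...) {
  cat(sprintf("<cell_type_call> %s (rise %.2f Hz vs rest %.2f Hz, p = %.3g)\n",
              x$label, x$rise_rest$rate_rise, x$rise_rest$rate_rest,
              x$rise_rest$p_value))
  invisible(x)
}

#' Fraction of calcium transients matched by electrical spikes
#'
#' For each detected transient, looks for at least one spike from any sorted
#' unit inside `[onset - window, peak_time]`; the matched fraction emulates
#' the correspondence between calcium spikes and electrically recorded
#' spikes. Monotone non-decreasing in the window length.
#'
#' @param transients [detect_transients()] output.
#' @param spike_times Numeric vector pooling all units' spike times (s).
#' @param window Pre-onset tolerance (s); default each transient's own rise
#'   duration.
#' @return List with `fraction` (`NA` and `undefined = TRUE` when there are
#'   no transients), `matched` logical vector, `unmatched` indices, `n`.
#' @export
transient_correspondence <- function(transients, spike_times,
                                     window = NULL) {
  n <- nrow(transients)
  if (n == 0)
    return(list(fraction = NA_real_, matched = logical(0),
                unmatched = integer(0), n = 0, undefined = TRUE))
  if (length(spike_times) == 0)
    return(list(fraction = 0, matched = rep(FALSE, n),
                unmatched = seq_len(n), n = n, undefined = FALSE))
  w <- window %||% (transients$peak_time - transients$onset)
  if (length(w) == 1) w <- rep(w, n)
  matched <- vapply(seq_len(n), function(i)
    any(spike_times >= transients$onset[i] - w[i] &
          spike_times <= transients$peak_time[i]), logical(1))
  list(fraction = mean(matched), matched = matched,
       unmatched = which(!matched), n = n, undefined = FALSE)
}

#' Minimum detectable burst size
#'
#' Smallest number of spikes n within one bin (default 200 ms) whose
#' linearly summed calcium transient exceeds `k` times the dF/F noise SD:
#' the detectability floor of the photodiode channel. Spikes are assumed
#' evenly spaced at the within-burst inter-spike interval, so the summed
#' peak is computed from the actual kernel, not just `n * unitary`.
#'
#' @param noise_sd dF/F noise SD.
#' @param kinetics A [calcium_kinetics()].
#' @param bin Burst window (s), default 0.2.
#' @param k Detection threshold multiplier, default 3.
#' @param isi Within-burst inter-spike interval (s), default 7.5 ms.
#' @param n_max Search cap.
#' @return Integer n*.
#' @export
min_detectable_burst <- function(noise_sd, kinetics, bin = 0.2, k = 3,
                                 isi = 7.5e-3, n_max = 1000) {
  if (kinetics$unitary_dff <= 0)
    stop("undefined: unitary amplitude is zero", call. = FALSE)
  stopifnot(noise_sd >= 0)
  tgrid <- seq(0, bin + 8 * kinetics$tau_decay, by = 1e-3)
  for (n in seq_len(n_max)) {
    times <- (seq_len(n) - 1) * isi
    if (max(times) > bin) break
    peak <- max(Reduce(`+`, lapply(times, function(t0)
      calcium_kernel(tgrid - t0, kinetics))))
    if (peak > k * noise_sd) return(n)
  }
  NA_integer_
}
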