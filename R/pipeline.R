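#' Reference scene configuration
#'
#' The default study conditions for the synthetic bimodal recordings: a
#' six-neuron population (four indicator-positive, two negative) above the
#' seven-electrode / photodiode pair, 100 s of recording, GCaMP6f-like
#' kinetics, the photodiode operating point (19.7 nA baseline, 155 pA dark,
#' 1.5 pA p-p noise), 8 uV extracellular channel noise, and - when
#' stimulation is enabled - a 0.5 Hz / 25% duty schedule starting at 40 s
#' (30 cycles) with a tonic-rate gain of 3 for opsin-connected neurons.
#'
#' @param synth A [synth_config()].
#' @param duration Recording duration (s).
#' @param kinetics A [calcium_kinetics()].
#' @param photodiode A [photodiode_params()].
#' @param geometry A [probe_geometry()].
#' @param noise_sd Extracellular channel noise SD (uV).
#' @param stim Logical: include optical stimulation.
#' @param stim_gain Tonic-rate multiplier during ON phases.
#' @param hp_cutoff,lp_cutoff dF/F filter settings (Hz).
#' @return A `scene_config` list.
#' @export
scene_config <- function(synth = synth_config(), duration = 100,
                         kinetics = calcium_kinetics(),
                         photodiode = photodiode_params(),
                         geometry = probe_geometry(), noise_sd = 8,
                         stim = FALSE, stim_gain = 3,
                         hp_cutoff = 0.1, lp_cutoff = 5) {
  structure(list(synth = synth, duration = duration, kinetics = kinetics,
                 photodiode = photodiode, geometry = geometry,
                 noise_sd = noise_sd, stim = stim, stim_gain = stim_gain,
                 hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff),
            class = "scene_config")
}

#' Generate a full synthetic session
#'
#' Runs the generator end to end for one seed: population, spike trains
#' (with stimulation when configured), photodiode current and 30 kHz
#' extracellular matrix.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; every random draw in the session derives
#'   from it.
#' @param render_extracellular Logical; skip the 30 kHz render when only the
#'   optical channel is needed.
#' @return A session list: `population`, `trains`, `photodiode`,
#'   `extracellular` (or `NULL`), `schedule` (or `NULL`), `seed`, `config`.
#' @export
generate_session <- function(config = scene_config(), seed = 1,
                             render_extracellular = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  if (config$synth$n_neurons < 1)
    stop("validation error: config specifies zero neurons", call. = FALSE)
  schedule <- if (isTRUE(config$stim))
    stim_schedule(t_start = 0.4 * config$duration, t_end = config$duration)
  else NULL
  pop <- generate_population(config$synth, seed = seed)
  trains <- generate_spike_trains(pop, schedule = schedule,
                                  duration = config$duration,
                                  stim_gain = if (is.null(schedule)) 1
                                              else config$stim_gain,
                                  seed = seed + 1)
  pd <- render_calcium_current(trains, pop, config$kinetics,
                               params = config$photodiode,
                               seed = seed + 2)
  ec <- if (render_extracellular)
    render_extracellular(trains, pop, config$geometry,
                         noise_sd = config$noise_sd, seed = seed + 3)
  else NULL
  list(population = pop, trains = trains, photodiode = pd,
       extracellular = ec, schedule = schedule, seed = seed,
       config = config)
}

#' Analyse a bimodal session
#'
#' The full analysis chain on a session: dF/F and transient detection on the
#' optical channel; band-pass, spike detection, sorting and trilateration on
#' the electrical channel; then per-unit rise/rest statistics, spike-count
#' regression, stimulation response (when a schedule exists) and the
#' cell-type call.
#'
#' @param session From [generate_session()] (or [read_session()] plus a
#'   rendered extracellular matrix).
#' @param k_transient Transient threshold multiplier.
#' @param k_spike Spike threshold multiplier.
#' @param alpha Classification significance level.
#' @return List: `dff`, `transients`, `filtered`, `units`, `positions`,
#'   `calls` (one `cell_type_call` per unit) and `calls_table` (data frame
#'   with the per-unit statistics).
#' @export
analyze_session <- function(session, k_transient = 3, k_spike = 4.5,
                            alpha = 0.05) {
  cfg <- session$config
  duration <- attr(session$trains, "duration")
  dff <- compute_dff(session$photodiode, hp_cutoff = cfg$hp_cutoff,
                     lp_cutoff = cfg$lp_cutoff)
  transients <- detect_transients(dff, k = k_transient, edge_exclusion = 2)
  filtered <- bandpass_ephys(session$extracellular)
  units <- sort_units(filtered, k = k_spike)
  positions <- lapply(units, trilaterate, geometry = cfg$geometry,
                      d0 = session$extracellular$d0)
  calls <- lapply(units, function(u) {
    rr <- rise_rest_rates(u$timestamps, transients, duration,
                          decay_time = cfg$kinetics$tau_decay)
    fit <- regression_spikes_dff(u$timestamps, dff)
    st <- if (!is.null(session$schedule))
      tryCatch(stim_response(u$timestamps, session$schedule, duration),
               error = function(e) NULL)
    else NULL
    classify_cell_type(rr, fit = fit, stim = st, alpha = alpha)
  })
  tbl <- do.call(rbind, lapply(seq_along(units), function(i) {
    u <- units[[i]]; cl <- calls[[i]]; ps <- positions[[i]]
    data.frame(
      unit = u$id, label = cl$label, n_spikes = u$n_spikes,
      primary_channel = u$primary_channel, snr = u$snr,
      x = ps$estimate[1], y = ps$estimate[2], z = ps$estimate[3],
      residual = ps$residual,
      rate_rise = cl$rise_rest$rate_rise, rate_rest = cl$rise_rest$rate_rest,
      p_rise_rest = cl$rise_rest$p_value,
      slope = if (!is.null(cl$fit)) cl$fit$slope else NA_real_,
      r2 = if (!is.null(cl$fit)) cl$fit$r_squared else NA_real_,
      rate_on = if (!is.null(cl$stim)) cl$stim$rate_on else NA_real_,
      rate_off = if (!is.null(cl$stim)) cl$stim$rate_off else NA_real_,
      rate_control = if (!is.null(cl$stim)) cl$stim$rate_control else NA_real_,
      p_on_off = if (!is.null(cl$stim)) cl$stim$p_on_off else NA_real_,
      p_off_control = if (!is.null(cl$stim)) cl$stim$p_off_control else NA_real_)
  }))
  list(dff = dff, transients = transients, filtered = filtered,
       units = units, positions = positions, calls = calls,
       calls_table = tbl)
}

#' Match sorted units to ground-truth neurons
#'
#' Greedy one-to-one assignment by spike-time agreement: a unit spike is
#' attributed to a neuron when it falls within `tol` of one of that neuron's
#' true spikes; each unit is matched to the neuron explaining the largest
#' share of its spikes, best shares first.
#'
#' @param units From [sort_units()].
#' @param trains Ground-truth [generate_spike_trains()].
#' @param tol Matching tolerance (s).
#' @return Data frame: `unit`, `neuron` (NA when unmatched), `agreement`
#'   (fraction of unit spikes explained).
#' @export
match_units_to_truth <- function(units, trains, tol = 1e-3) {
  if (!length(units))
    return(data.frame(unit = integer(0), neuron = integer(0),
                      agreement = numeric(0)))
  share <- sapply(trains, function(ts) vapply(units, function(u) {
    if (!length(u$timestamps) || !length(ts)) return(0)
    mean(vapply(u$timestamps, function(s) any(abs(ts - s) <= tol),
                logical(1)))
  }, numeric(1)))
  share <- matrix(share, nrow = length(units))
  nsp <- vapply(units, function(u) length(u$timestamps), numeric(1))
  res <- data.frame(unit = vapply(units, function(u) u$id, numeric(1)),
                    neuron = NA_integer_, agreement = NA_real_)
  taken <- logical(ncol(share))
  # assign largest explained spike counts first, so a neuron goes to its
  # main cluster rather than to a small split-off with a purer share
  explained <- share * nsp
  for (k in order(-apply(explained, 1, max))) {
    j <- which.max(ifelse(taken, -1, explained[k, ]))
    if (share[k, j] > 0.5 && !taken[j]) {
      res$neuron[k] <- as.integer(names(trains)[j])
      res$agreement[k] <- share[k, j]
      taken[j] <- TRUE
    }
  }
  res
}

#' Run the full pipeline from a configuration
#'
#' Generates a session, analyses both channels, classifies every sorted
#' unit, and writes the report tables (`calls.csv`, `units.csv`,
#' `transients.csv`, `meta.json`) to `out_dir`. Byte-identical outputs for
#' identical `(config, seed)`.
#'
#' @param config `NULL` for the reference scene, a [scene_config()], or a
#'   path to a YAML file with any of: `n_neurons`, `fraction_positive`,
#'   `duration`, `stim`, `stim_gain`, `noise_sd`, `hp_cutoff`, `lp_cutoff`,
#'   `unitary_dff`, `tau_rise`, `tau_decay`.
#' @param seed Integer seed.
#' @param out_dir Output directory; created. `NULL` skips writing.
#' @return List: the `session`, the `analysis`, the unit-truth `matching`,
#'   and `accuracy` (fraction of matched units whose call agrees with the
#'   ground-truth flag).
#' @export
run_pipeline <- function(config = NULL, seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- load_scene_yaml(config)
  if (is.null(config)) config <- scene_config()
  session <- generate_session(config, seed = seed)
  analysis <- analyze_session(session)
  matching <- match_units_to_truth(analysis$units, session$trains)
  truth <- session$population$indicator_positive
  ok <- !is.na(matching$neuron)
  agree <- vapply(which(ok), function(i) {
    lbl <- analysis$calls_table$label[analysis$calls_table$unit ==
                                        matching$unit[i]]
    want <- truth[session$population$id == matching$neuron[i]]
    (lbl == "indicator_positive") == want && lbl != "unclassified"
  }, logical(1))
  accuracy <- if (any(ok)) mean(agree) else NA_real_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_exact(analysis$calls_table[, c(
      "unit", "label", "rate_rise", "rate_rest", "p_rise_rest", "slope",
      "r2", "rate_on", "rate_off", "rate_control", "p_on_off",
      "p_off_control")], file.path(out_dir, "calls.csv"))
    write_table_exact(analysis$calls_table[, c(
      "unit", "n_spikes", "primary_channel", "snr", "x", "y", "z",
      "residual")], file.path(out_dir, "units.csv"))
    write_table_exact(as.data.frame(analysis$transients),
                      file.path(out_dir, "transients.csv"))
    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash(config),
           accuracy = accuracy,
           n_units = length(analysis$units),
           package_version = as.character(utils::packageVersion("fluorephys"))),
      file.path(out_dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  list(session = session, analysis = analysis, matching = matching,
       accuracy = accuracy)
}

load_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("n_neurons", "fraction_positive", "duration",
                             "stim", "stim_gain", "noise_sd", "hp_cutoff",
                             "lp_cutoff", "unitary_dff", "tau_rise",
                             "tau_decay"))
  if (length(bad))
    stop("validation error in config: unknown field(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  sy <- synth_config(n_neurons = y$n_neurons %||% 6,
                     fraction_positive = y$fraction_positive %||% (4 / 6))
  kin <- calcium_kinetics(tau_rise = y$tau_rise %||% 0.05,
                          tau_decay = y$tau_decay %||% 0.4,
                          unitary_dff = y$unitary_dff %||% 0.01)
  scene_config(synth = sy, duration = y$duration %||% 100, kinetics = kin,
               noise_sd = y$noise_sd %||% 8, stim = isTRUE(y$stim),
               stim_gain = y$stim_gain %||% 3,
               hp_cutoff = y$hp_cutoff %||% 0.1,
               lp_cutoff = y$lp_cutoff %||% 5)
}

#' Classify a scene from the optical evidence alone
#'
#' Lightweight classification path used for seed-robustness sweeps: the
#' ground-truth spike trains stand in for sorted units (the sorter and the
#' trilateration solver are validated separately), the calcium channel is
#' rendered and analysed in full, and every neuron receives a cell-type
#' call.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return List: `labels`, `truth`, `all_correct`, `accuracy`.
#' @export
classify_scene_optical <- function(config = scene_config(), seed = 1,
                                   alpha = 0.05) {
  session <- generate_session(config, seed = seed,
                              render_extracellular = FALSE)
  dff <- compute_dff(session$photodiode, hp_cutoff = config$hp_cutoff,
                     lp_cutoff = config$lp_cutoff)
  transients <- detect_transients(dff, edge_exclusion = 2)
  duration <- attr(session$trains, "duration")
  labels <- vapply(seq_len(nrow(session$population)), function(i) {
    rr <- rise_rest_rates(session$trains[[i]], transients, duration,
                          decay_time = config$kinetics$tau_decay)
    classify_cell_type(rr, alpha = alpha)$label
  }, character(1))
  truth <- session$population$indicator_positive
  correct <- (labels == "indicator_positive") == truth &
    labels != "unclassified"
  list(labels = labels, truth = truth, all_correct = all(correct),
       accuracy = mean(correct))
}
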