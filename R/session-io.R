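# Full-precision CSV helpers: numbers written with 17 significant digits so
# a write/read round trip reproduces doubles bit-exactly.
write_table_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

read_table_exact <- function(path, double_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in intersect(double_cols, names(df))) df[[j]] <- as.double(df[[j]])
  df
}

#' Write a recording session to a directory container
#'
#' Persists a synthetic (or analysed) session as plain-text tables plus JSON
#' metadata: `photodiode.csv` (60 Hz current trace), `ground_truth.csv`,
#' `spikes.csv` (neuron id, time), `schedule.json`, and `meta.json`
#' (sampling rates, seed, config hash, package version). The 30 kHz
#' extracellular matrix is written only when `include_raw = TRUE`
#' (`extracellular.csv`); it is large and can always be regenerated from the
#' seed. Doubles are serialized at full precision so the round trip is
#' bit-exact.
#'
#' @param session List with elements `photodiode` (a `photodiode_trace`),
#'   `trains`, `population`, optional `schedule`, optional `extracellular`,
#'   `seed`, `config`.
#' @param dir Output directory (created if needed).
#' @param include_raw Also write the 30 kHz matrix.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, include_raw = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- session$photodiode
  write_table_exact(data.frame(current = pd$current),
                    file.path(dir, "photodiode.csv"))
  write_table_exact(session$population, file.path(dir, "ground_truth.csv"))
  sp <- do.call(rbind, lapply(names(session$trains), function(id)
    if (length(session$trains[[id]]))
      data.frame(neuron = as.integer(id), time = session$trains[[id]])
    else NULL))
  if (is.null(sp)) sp <- data.frame(neuron = integer(0), time = numeric(0))
  write_table_exact(sp, file.path(dir, "spikes.csv"))
  if (!is.null(session$schedule))
    jsonlite::write_json(unclass(session$schedule),
                         file.path(dir, "schedule.json"),
                         auto_unbox = TRUE, digits = NA)
  if (include_raw && !is.null(session$extracellular)) {
    ec <- as.data.frame(session$extracellular$samples)
    names(ec) <- paste0("ch", seq_len(ncol(ec)))
    write_table_exact(ec, file.path(dir, "extracellular.csv"))
  }
  meta <- list(
    photodiode_sampling_rate = pd$sampling_rate,
    extracellular_sampling_rate =
      if (!is.null(session$extracellular))
        session$extracellular$sampling_rate else NULL,
    duration = attr(session$trains, "duration"),
    seed = session$seed,
    config_hash = if (!is.null(session$config))
      config_hash(session$config) else NULL,
    package_version = as.character(utils::packageVersion("fluorephys")))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session container
#'
#' Inverse of [write_session()]; arrays round-trip bit-exactly.
#'
#' @param dir Session directory.
#' @return List with `photodiode`, `population`, `trains`, `schedule`
#'   (if present), `extracellular` (if present), `meta`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pd <- read_table_exact(file.path(dir, "photodiode.csv"), "current")
  pop <- read_table_exact(file.path(dir, "ground_truth.csv"),
                          c("x", "y", "z", "baseline_rate", "burst_rate",
                            "soma_amplitude"))
  sp <- read_table_exact(file.path(dir, "spikes.csv"), "time")
  trains <- lapply(pop$id, function(id) sp$time[sp$neuron == id])
  names(trains) <- pop$id
  attr(trains, "duration") <- meta$duration
  class(trains) <- "spike_trains"
  out <- list(
    photodiode = structure(list(current = pd$current,
                                sampling_rate = meta$photodiode_sampling_rate,
                                params = NULL),
                           class = "photodiode_trace"),
    population = pop, trains = trains, meta = meta)
  sched_path <- file.path(dir, "schedule.json")
  if (file.exists(sched_path)) {
    s <- jsonlite::read_json(sched_path, simplifyVector = TRUE)
    out$schedule <- structure(s, class = "stim_schedule")
  }
  raw_path <- file.path(dir, "extracellular.csv")
  if (file.exists(raw_path)) {
    ec <- utils::read.csv(raw_path)
    out$extracellular <- structure(
      list(samples = as.matrix(ec),
           sampling_rate = meta$extracellular_sampling_rate),
      class = "extracellular_recording")
  }
  out
}

# Stable short hash of a configuration list (polynomial rolling hash over
# its deparsed form); provenance only, not cryptographic.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
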