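# CSV interchange formats. All files are UTF-8, '.' decimal, one header row;
# object-level metadata travels in leading comment lines of the form
# "#key=value" so a file round-trips to the same object.

write_meta <- function(con, meta) {
  writeLines(sprintf("#%s=%s", names(meta), vapply(meta, as.character, "")),
             con)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50)
  ml <- grep("^#", lines, value = TRUE)
  kv <- regmatches(ml, regexec("^#([^=]+)=(.*)$", ml))
  keys <- vapply(kv, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  vals <- vapply(kv, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  stats::setNames(as.list(vals), keys)
}

read_body <- function(path, required, what) {
  d <- tryCatch(utils::read.csv(path, comment.char = "#"),
                error = function(e)
                  stop_invalid("malformed ", what, " file '", path, "': ",
                               conditionMessage(e)))
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop_invalid(what, " file '", path, "' lacks required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 " (found: ", paste(names(d), collapse = ", "), ")")
  d
}

#' Write / read a current trace CSV
#'
#' Columns \code{time_s, current_pa}; sample rate, cell id and holding
#' potential in \code{#key=value} header lines. \code{invert = TRUE} flips
#' the sign at ingest so inward (negative-going) recordings are stored as
#' the positive magnitudes the analyses expect.
#'
#' @param trace A [current_trace()].
#' @param path File path.
#' @param invert Flip the sign of the current at ingest.
#' @return \code{read_trace_csv}: a [current_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(format = "synphys_trace",
                       sample_rate_hz = trace$sample_rate_hz,
                       cell_id = trace$cell_id,
                       holding_potential_mv = trace$holding_potential_mv))
  t <- (seq_along(trace$samples) - 1) / trace$sample_rate_hz
  utils::write.csv(data.frame(time_s = t, current_pa = trace$samples),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, invert = FALSE) {
  meta <- read_meta(path)
  if (!identical(meta$format, "synphys_trace"))
    stop_invalid("'", path, "' is not a trace CSV (missing #format=synphys_trace)")
  d <- read_body(path, c("time_s", "current_pa"), "trace")
  x <- if (invert) -d$current_pa else d$current_pa
  current_trace(x, as.numeric(meta$sample_rate_hz),
                holding_potential_mv = as.numeric(meta$holding_potential_mv),
                cell_id = meta$cell_id)
}

#' Write / read an evoked trial table CSV
#'
#' Columns \code{trial, stim_time_s, amplitude_pa} plus optional
#' \code{failure} (0/1) and \code{true_k}.
#'
#' @param trials An [evoked_trials()].
#' @param path File path.
#' @return \code{read_trials_csv}: an [evoked_trials()].
#' @export
write_trials_csv <- function(trials, path) {
  stopifnot(inherits(trials, "evoked_trials"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(format = "synphys_trials", cell_id = trials$cell_id))
  d <- data.frame(trial = seq_along(trials$amplitudes_pa),
                  stim_time_s = trials$stim_times_s,
                  amplitude_pa = trials$amplitudes_pa)
  if (!anyNA(trials$failure_flags)) d$failure <- as.integer(trials$failure_flags)
  if (!is.null(trials$true_k)) d$true_k <- trials$true_k
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$format, "synphys_trials"))
    stop_invalid("'", path, "' is not a trial-table CSV")
  d <- read_body(path, c("trial", "stim_time_s", "amplitude_pa"), "trial-table")
  evoked_trials(d$amplitude_pa, stim_times_s = d$stim_time_s,
                failure_flags = if ("failure" %in% names(d))
                  as.logical(d$failure) else NULL,
                true_k = d$true_k, cell_id = meta$cell_id)
}

#' Write / read an event table CSV
#'
#' Columns \code{cell_id, time_s, amplitude_pa}; the observation duration in
#' a header line.
#'
#' @param train An [event_train()].
#' @param path File path.
#' @return \code{read_events_csv}: an [event_train()].
#' @export
write_events_csv <- function(train, path) {
  stopifnot(inherits(train, "event_train"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(format = "synphys_events", duration_s = train$duration_s))
  utils::write.csv(data.frame(cell_id = train$cell_id,
                              time_s = train$times_s,
                              amplitude_pa = train$amplitudes_pa),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$format, "synphys_events"))
    stop_invalid("'", path, "' is not an event-table CSV")
  d <- read_body(path, c("cell_id", "time_s", "amplitude_pa"), "event-table")
  event_train(d$time_s, d$amplitude_pa,
              duration_s = as.numeric(meta$duration_s),
              cell_id = if (nrow(d)) d$cell_id[1] else "cell")
}

#' Write / read an actogram CSV
#'
#' Header lines carry animal id, genotype, age, light schedule and bin
#' width; the body is the day-by-bin count matrix with a \code{day} column
#' and \code{bin_<start-minute>} columns.
#'
#' @param act An [actogram()].
#' @param path File path.
#' @return \code{read_actogram_csv}: an [actogram()].
#' @export
write_actogram_csv <- function(act, path) {
  stopifnot(inherits(act, "actogram"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(format = "synphys_actogram", animal_id = act$animal_id,
                       genotype = act$genotype_label, age = act$age_label,
                       lights_on_min = act$lights_on_min,
                       lights_off_min = act$lights_off_min,
                       bin_min = act$bin_min))
  d <- as.data.frame(act$counts)
  names(d) <- paste0("bin_", (seq_len(ncol(d)) - 1) * act$bin_min)
  d <- cbind(day = seq_len(nrow(d)) - 1, d)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_actogram_csv
#' @export
read_actogram_csv <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$format, "synphys_actogram"))
    stop_invalid("'", path, "' is not an actogram CSV")
  need <- c("animal_id", "lights_on_min", "lights_off_min", "bin_min")
  if (!all(need %in% names(meta)))
    stop_invalid("actogram CSV '", path, "' lacks header line(s): ",
                 paste(setdiff(need, names(meta)), collapse = ", "))
  d <- read_body(path, "day", "actogram")
  counts <- as.matrix(d[grep("^bin_", names(d))])
  actogram(counts, bin_min = as.numeric(meta$bin_min),
           lights_on_min = as.numeric(meta$lights_on_min),
           lights_off_min = as.numeric(meta$lights_off_min),
           animal_id = meta$animal_id,
           genotype_label = if (is.null(meta$genotype)) "" else meta$genotype,
           age_label = if (is.null(meta$age)) "" else meta$age)
}

#' Write / read a fura-2 ratio trace CSV
#'
#' Columns \code{time_s, ratio}; calibration constants in header lines.
#'
#' @param trace A [fura_trace()].
#' @param path File path.
#' @return \code{read_fura_csv}: a [fura_trace()].
#' @export
write_fura_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fura_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(format = "synphys_fura", cell_id = trace$cell_id,
                       r_min = trace$calib$r_min, r_max = trace$calib$r_max,
                       kd_nm = trace$calib$kd_nm, beta = trace$calib$beta))
  utils::write.csv(data.frame(time_s = trace$time_s, ratio = trace$ratio),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fura_csv
#' @export
read_fura_csv <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$format, "synphys_fura"))
    stop_invalid("'", path, "' is not a fura ratio-trace CSV")
  d <- read_body(path, c("time_s", "ratio"), "fura-trace")
  fura_trace(d$time_s, d$ratio,
             calib = calibration_constants(as.numeric(meta$r_min),
                                           as.numeric(meta$r_max),
                                           as.numeric(meta$kd_nm),
                                           as.numeric(meta$beta)),
             cell_id = meta$cell_id)
}

#' Read a concentration-response points CSV
#'
#' Columns \code{concentration_um, inhibition_pct} with optional
#' \code{sem_pct} and \code{n_cells}.
#'
#' @param path File path.
#' @return A data frame suitable for [fit_hill()].
#' @export
read_dose_points_csv <- function(path) {
  read_body(path, c("concentration_um", "inhibition_pct"), "dose-response")
}

#' Read a 2x2 group-summary CSV
#'
#' Columns \code{age, genotype, mean, sem, n}, one row per cell; an optional
#' \code{measure} column selects one table from a multi-measure file.
#'
#' @param path File path.
#' @param measure Measure label to select when the file stacks several
#'   tables.
#' @return A [group_summary_2x2()] object.
#' @export
read_group_summary_csv <- function(path, measure = NULL) {
  d <- read_body(path, c("age", "genotype", "mean", "sem", "n"),
                 "group-summary")
  if (!is.null(measure)) {
    if (!"measure" %in% names(d))
      stop_invalid("file has no 'measure' column to select '", measure, "'")
    d <- d[d$measure == measure, , drop = FALSE]
    if (nrow(d) == 0) stop_invalid("no rows with measure '", measure, "'")
  }
  group_summary_2x2(d$age, d$genotype, d$mean, d$sem, d$n,
                    measure = if (is.null(measure)) "" else measure)
}

#' Concentration-response table for calcium-current inhibition
#'
#' The five published mean percent-inhibition points (with SEM and cell
#' counts) for amitriptyline block of high-voltage-activated calcium
#' currents, shipped with the package as the canonical input to
#' [fit_hill()].
#'
#' @return Data frame with columns \code{concentration_um},
#'   \code{inhibition_pct}, \code{sem_pct}, \code{n_cells}.
#' @export
ami_dose_response <- function() {
  read_dose_points_csv(system.file("extdata", "ami_calcium_doseresponse.csv",
                                   package = "synphys"))
}

#' Published wheel-running 2x2 summaries
#'
#' Per-group (age x genotype) mean, SEM and n for the three circadian
#' measures: total daily activity (revs/24 h), phase angle of entrainment
#' (min), and day-to-day onset variability (min).
#'
#' @param measure One of \code{"daily_activity"}, \code{"phase_angle"},
#'   \code{"onset_variability"}; with no argument the full stacked data
#'   frame is returned.
#' @return A [group_summary_2x2()] (or the raw data frame).
#' @export
wheel_running_summary <- function(measure) {
  path <- system.file("extdata", "wheel_running_summaries.csv",
                      package = "synphys")
  if (missing(measure)) return(utils::read.csv(path))
  read_group_summary_csv(path, measure = measure)
}
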