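#' Daily activity onset by the 10%-of-peak rule
#'
#' The onset for a given circadian day is the start minute of the first bin,
#' scanning the day from lights-on (wrapping past midnight back to the bins
#' before lights-on), whose count reaches \code{fraction} of the peak bin
#' count. The peak is that day's maximum bin by default
#' (\code{peak_scope = "day"}), or the whole record's maximum bin
#' (\code{"record"}). Days whose total activity falls below
#' \code{min_daily_revs} are unanalyzable and return NA, never a spurious
#' zero-minute onset.
#'
#' The rule is invariant to multiplying a day's counts by a positive
#' constant (the threshold is relative).
#'
#' @param act An [actogram()].
#' @param day Day index, 1-based.
#' @param fraction Fraction of peak defining the onset threshold.
#' @param peak_scope \code{"day"} (per-cycle peak) or \code{"record"}.
#' @param min_daily_revs Minimum daily total for a day to be analyzable.
#' @return Onset in minutes-from-midnight, or NA.
#' @export
detect_daily_onset <- function(act, day, fraction = 0.10,
                               peak_scope = c("day", "record"),
                               min_daily_revs = 50) {
  stopifnot(inherits(act, "actogram"))
  peak_scope <- match.arg(peak_scope)
  if (day < 1 || day > nrow(act$counts)) stop_invalid("invalid day index")
  x <- act$counts[day, ]
  if (sum(x) < min_daily_revs || all(x == 0)) return(NA_real_)
  peak <- if (peak_scope == "day") max(x) else max(act$counts)
  thr <- fraction * peak
  nb <- length(x)
  start_bin <- floor(act$lights_on_min / act$bin_min)  # 0-based
  scan <- (start_bin + 0:(nb - 1)) %% nb + 1           # circadian scan order
  hit <- scan[which(x[scan] >= thr)[1]]
  if (is.na(hit)) return(NA_real_)
  (hit - 1) * act$bin_min
}

#' Onsets for every day of an actogram
#'
#' @inheritParams detect_daily_onset
#' @param ... Passed to [detect_daily_onset()].
#' @return Numeric vector of onset minutes (NA for unanalyzable days).
#' @export
activity_onsets <- function(act, ...) {
  vapply(seq_len(nrow(act$counts)), function(d)
    detect_daily_onset(act, d, ...), numeric(1))
}

#' Phase angle of entrainment by least-squares regression
#'
#' Fits an ordinary least-squares line of onset minute against day index
#' over the non-missing onsets (day indices keep their true spacing) and
#' evaluates it at the midpoint of the analysis window, which under OLS
#' equals the mean onset. The phase angle is
#' \deqn{\Psi = \mathrm{lights\_off} - \mathrm{onset},}
#' positive when onsets precede lights-off, negative when they follow it.
#'
#' @param onsets_min Per-day onset minutes (NA = missing), e.g. from
#'   [activity_onsets()].
#' @param lights_off_min Lights-off time (minutes from midnight).
#' @return Phase angle in minutes.
#' @examples
#' entrainment_phase(rep(1100, 10), 1080)  # -20 (onset after lights-off)
#' @export
entrainment_phase <- function(onsets_min, lights_off_min = 1080) {
  ok <- !is.na(onsets_min)
  if (sum(ok) < 3)
    stop_invalid("at least 3 non-missing onsets required")
  day <- which(ok) - 1
  y <- onsets_min[ok]
  fit <- stats::lm.fit(cbind(1, day), y)
  mid <- (min(day) + max(day)) / 2
  onset_mid <- fit$coefficients[1] + fit$coefficients[2] * mid
  unname(lights_off_min - onset_mid)
}

#' Day-to-day onset variability
#'
#' Mean absolute difference between onsets on successive days, computed over
#' consecutive non-missing pairs only (pairs spanning a missing day are
#' excluded).
#'
#' @param onsets_min Per-day onset minutes (NA = missing).
#' @return Mean absolute successive difference (minutes).
#' @examples
#' onset_variability(c(1080, 1110, 1090))  # mean(30, 20) = 25
#' @export
onset_variability <- function(onsets_min) {
  if (length(onsets_min) < 2) stop_invalid("at least 2 onsets required")
  a <- onsets_min[-length(onsets_min)]
  b <- onsets_min[-1]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop_invalid("no consecutive pairs of non-missing onsets")
  mean(abs(b[ok] - a[ok]))
}

#' Total daily activity
#'
#' Average wheel revolutions per 24 h over the recorded days.
#'
#' @param act An [actogram()].
#' @return Mean daily revolutions.
#' @export
total_activity <- function(act) {
  stopifnot(inherits(act, "actogram"))
  mean(rowSums(act$counts))
}

#' Double-plotted actogram display matrix
#'
#' Row d of the display is day d concatenated with day d+1 (48 h wide), the
#' conventional double plot. Dark-phase shading coordinates (minutes on the
#' 0-2880 display axis) are attached as attributes.
#'
#' @param act An [actogram()] with at least 2 days.
#' @param double_plot If FALSE, returns the raw counts matrix.
#' @return A matrix with attributes \code{bin_min} and \code{dark_spans}
#'   (two-column matrix of shading start/end minutes).
#' @export
actogram_matrix <- function(act, double_plot = TRUE) {
  stopifnot(inherits(act, "actogram"))
  if (!double_plot) return(act$counts)
  nd <- nrow(act$counts)
  if (nd < 2) stop_invalid("double plot requires at least 2 days")
  m <- cbind(act$counts[-nd, , drop = FALSE], act$counts[-1, , drop = FALSE])
  attr(m, "bin_min") <- act$bin_min
  attr(m, "dark_spans") <- rbind(
    c(act$lights_off_min, 1440 + act$lights_on_min),
    c(1440 + act$lights_off_min, 2880))
  m
}

#' @export
plot.actogram <- function(x, ...) {
  m <- actogram_matrix(x)
  nd <- nrow(m)
  graphics::plot(NULL, xlim = c(0, 2880), ylim = c(nd + 0.5, 0.5),
                 xlab = "time (min, double-plotted 48 h)", ylab = "day",
                 main = x$animal_id, xaxs = "i", ...)
  spans <- attr(m, "dark_spans")
  for (i in seq_len(nrow(spans)))
    graphics::rect(spans[i, 1], nd + 0.5, spans[i, 2], 0.5,
                   col = grDevices::grey(0.92), border = NA)
  mx <- max(m, 1)
  for (d in seq_len(nd)) {
    on <- which(m[d, ] > 0)
    if (length(on))
      graphics::segments((on - 1) * x$bin_min, d,
                         (on - 1) * x$bin_min, d - 0.9 * m[d, on] / mx)
  }
  invisible(x)
}

#' Entrainment summary of one actogram
#'
#' Runs onset detection, the least-squares phase angle, day-to-day onset
#' variability and total daily activity on a single animal's record.
#'
#' @param act An [actogram()].
#' @param fraction,peak_scope,min_daily_revs Passed to
#'   [detect_daily_onset()].
#' @return An object of class \code{entrainment_summary} with fields
#'   \code{psi_min}, \code{onset_variability_min}, \code{total_daily_activity},
#'   \code{n_days_used}, \code{onsets_min}, and metadata.
#' @export
entrainment_summary <- function(act, fraction = 0.10,
                                peak_scope = c("day", "record"),
                                min_daily_revs = 50) {
  stopifnot(inherits(act, "actogram"))
  onsets <- activity_onsets(act, fraction = fraction,
                            peak_scope = match.arg(peak_scope),
                            min_daily_revs = min_daily_revs)
  structure(list(
    psi_min = entrainment_phase(onsets, act$lights_off_min),
    onset_variability_min = onset_variability(onsets),
    total_daily_activity = total_activity(act),
    n_days_used = sum(!is.na(onsets)),
    onsets_min = onsets,
    animal_id = act$animal_id, genotype_label = act$genotype_label,
    age_label = act$age_label), class = "entrainment_summary")
}

#' @export
print.entrainment_summary <- function(x, ...) {
  cat(sprintf("<entrainment_summary> %s (%s %s)\n", x$animal_id,
              x$age_label, x$genotype_label))
  cat(sprintf("  phase angle Psi: %.2f min (%s lights-off)\n", x$psi_min,
              if (x$psi_min >= 0) "onset before" else "onset after"))
  cat(sprintf("  day-to-day onset variability: %.2f min\n",
              x$onset_variability_min))
  cat(sprintf("  total daily activity: %.0f revs/24 h over %d analyzable days\n",
              x$total_daily_activity, x$n_days_used))
  invisible(x)
}
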