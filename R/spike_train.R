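# Spike trains and per-unit discharge statistics with inclusion filters.

#' Construct a spike train
#'
#' @param times discharge times in ms, strictly increasing.
#' @param duration recording duration in ms (defaults to the last spike).
#' @param source one of "simulated", "external", "surrogate".
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration = NULL,
                        source = c("simulated", "external", "surrogate")) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0))
    stop("discharge times must be strictly increasing")
  if (is.null(duration))
    duration <- if (length(times)) times[length(times)] else 0
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("discharge times must lie in [0, duration]")
  structure(times, duration = duration, source = source,
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train (%s): %d discharges over %.1f s\n",
              attr(x, "source"), length(x), attr(x, "duration") / 1000))
  invisible(x)
}

#' Background discharge rate
#'
#' Mean discharge rate over the union of the pre-stimulus windows
#' `[onset - window, onset)`: the spike count inside those windows divided
#' by the total window time.  A train with no spikes has rate 0 (not
#' undefined), so recruitment counting is total-ordered.
#'
#' @param train a [spike_train()] or numeric spike times in ms.
#' @param stimuli a [stimulus_train()] or numeric onset times in ms.
#' @param window pre-stimulus window length in ms (default 500).
#' @return Background discharge rate in Hz.
#' @export
background_dr <- function(train, stimuli, window = 500) {
  on <- as.numeric(stimuli)
  if (!length(on)) stop("at least one stimulus is required")
  lo <- on - window
  if (all(lo < 0)) stop("no pre-stimulus window available before time 0")
  lo <- pmax(lo, 0)
  tt <- as.numeric(train)
  n_in <- sum(vapply(seq_along(on), function(k)
    sum(tt >= lo[k] & tt < on[k]), numeric(1)))
  total_ms <- sum(on - lo)
  1000 * n_in / total_ms
}

#' Coefficient of variation of the interspike intervals
#'
#' `100 * SD(ISI) / mean(ISI)` over ISIs that do not overlap any
#' post-stimulus interval `(onset, onset + exclude_post]`.  The exclusion
#' keeps the statistic an index of background membrane noise rather than
#' of the evoked response.
#'
#' @inheritParams background_dr
#' @param exclude_post length of the post-stimulus exclusion interval (ms);
#'   set to 0 to use all ISIs.
#' @param min_isis minimal number of ISIs required (default 3).
#' @return CoV of the ISIs in percent.
#' @export
cov_isi <- function(train, stimuli = numeric(0), exclude_post = 100,
                    min_isis = 3) {
  tt <- as.numeric(train)
  if (length(tt) < 2) stop("too few discharges to form interspike intervals")
  a <- tt[-length(tt)]
  b <- tt[-1]
  keep <- rep(TRUE, length(a))
  for (on in as.numeric(stimuli)) {
    keep <- keep & !(a < on + exclude_post & b > on)
  }
  isi <- (b - a)[keep]
  if (length(isi) < min_isis)
    stop("fewer than ", min_isis, " usable interspike intervals")
  100 * sd(isi) / mean(isi)
}

#' Unit inclusion filter
#'
#' Applies the discharge-statistics filters used before reflex analysis:
#' simulated units need a background rate of at least 7 Hz, externally
#' recorded units at least 5 Hz, and both need an ISI coefficient of
#' variation of at most 30 %.
#'
#' @param dr background discharge rate in Hz.
#' @param cov ISI coefficient of variation in percent.
#' @param mode "simulated" or "experimental".
#' @return Logical: keep the unit?
#' @export
include_unit <- function(dr, cov, mode = c("simulated", "experimental")) {
  mode <- match.arg(mode)
  dr_min <- if (mode == "simulated") 7 else 5
  dr >= dr_min & cov <= 30
}

#' Discharge statistics of one unit
#'
#' Convenience wrapper: background rate, ISI CoV, number of usable ISIs
#' and the inclusion flag.
#'
#' @inheritParams background_dr
#' @inheritParams include_unit
#' @return A list of class `discharge_stats` with elements `dr`, `cov_isi`,
#'   `n_isi`, `included`.
#' @export
discharge_stats <- function(train, stimuli,
                            mode = c("simulated", "experimental")) {
  mode <- match.arg(mode)
  dr <- background_dr(train, stimuli)
  cv <- tryCatch(cov_isi(train, stimuli), error = function(e) NA_real_)
  n_isi <- max(length(as.numeric(train)) - 1, 0)
  inc <- if (is.na(cv)) FALSE else include_unit(dr, cv, mode)
  structure(list(dr = dr, cov_isi = cv, n_isi = n_isi, included = inc,
                 mode = mode), class = "discharge_stats")
}

#' @export
print.discharge_stats <- function(x, ...) {
  cat(sprintf("DR %.2f Hz, CoV_ISI %s%%, %s (%s mode)\n", x$dr,
              ifelse(is.na(x$cov_isi), "NA", sprintf("%.1f", x$cov_isi)),
              if (x$included) "included" else "excluded", x$mode))
  invisible(x)
}

#' Read spike trains and stimulus times from CSV
#'
#' Spike file: two columns `unit` (id) and `time_ms`; stimulus file: one
#' column `time_ms`.  Times must be strictly increasing within a unit.
#'
#' @param spike_file path to the spike CSV.
#' @param stimulus_file optional path to the stimulus CSV.
#' @return A list with `trains` (named list of [spike_train()]) and
#'   `stimuli` (numeric onsets or NULL).
#' @export
read_spike_trains <- function(spike_file, stimulus_file = NULL) {
  d <- read.csv(spike_file)
  if (!all(c("unit", "time_ms") %in% names(d)))
    stop("spike file needs columns 'unit' and 'time_ms'")
  trains <- lapply(split(d$time_ms, d$unit), function(tt) {
    if (is.unsorted(tt, strictly = TRUE))
      stop("discharge times must be strictly increasing within a unit")
    spike_train(tt, source = "external")
  })
  stimuli <- NULL
  if (!is.null(stimulus_file)) {
    s <- read.csv(stimulus_file)
    stimuli <- s[[if ("time_ms" %in% names(s)) "time_ms" else 1]]
  }
  list(trains = trains, stimuli = stimuli)
}

#' Write spike trains and stimulus times to CSV
#'
#' @param trains named list of [spike_train()] objects (or numeric vectors).
#' @param spike_file output path for the spike CSV.
#' @param stimuli optional stimulus onsets in ms.
#' @param stimulus_file output path for the stimulus CSV.
#' @return Invisibly, the spike file path.
#' @export
write_spike_trains <- function(trains, spike_file, stimuli = NULL,
                               stimulus_file = NULL) {
  if (is.null(names(trains))) names(trains) <- seq_along(trains)
  d <- do.call(rbind, lapply(names(trains), function(id)
    data.frame(unit = id, time_ms = as.numeric(trains[[id]]))))
  write.csv(d, spike_file, row.names = FALSE)
  if (!is.null(stimuli) && !is.null(stimulus_file))
    write.csv(data.frame(time_ms = as.numeric(stimuli)), stimulus_file,
              row.names = FALSE)
  invisible(spike_file)
}
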