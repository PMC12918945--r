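# Pool-level simulation studies: recruitment counts at a constant mean
# drive and the full activation-level reflex study.

# deterministic sub-seeds below 2^31 derived from (seed, level, neuron)
.sub_seed <- function(seed, level, neuron = 0L) {
  (as.integer(seed) * 7919L + as.integer(level) * 104729L +
     as.integer(neuron) * 131L) %% 2147483629L
}

#' Fraction of the pool firing sustainedly at a constant mean drive
#'
#' Simulates every neuron of the pool for `duration` ms under the default
#' noise configuration (common band-pass noise shared by the pool plus
#' independent low-pass noise per neuron) at the given mean drive, and
#' counts the neurons whose discharge rate after the transient reaches the
#' sustained-firing bound (7 Hz, the same bound as the simulated-mode
#' inclusion filter).
#'
#' @param pool an [mn_pool()].
#' @param drive mean common drive in nA.
#' @param duration simulated time per neuron in ms (default 10000).
#' @param transient discarded initial interval in ms.
#' @param seed integer seed.
#' @param rate_min sustained-firing bound in Hz (default 7).
#' @param dt integration step in ms.
#' @return A list with `fraction`, `n_firing`, `rates` (per-neuron Hz).
#' @export
firing_fraction <- function(pool, drive, duration = 10000, transient = 500,
                            seed = 1L, rate_min = 7, dt = 0.05) {
  stopifnot(inherits(pool, "mn_pool"))
  cfg <- input_config(mean_drive = drive, duration = duration, dt = dt,
                      seed = .sub_seed(seed, 1L))
  common <- as.numeric(common_input(cfg))
  ratio <- round(cfg$noise_dt / dt)
  n <- nrow(pool)
  rates <- numeric(n)
  for (i in seq_len(n)) {
    nzc <- .indep_noise_coarse(cfg, .sub_seed(seed, 1L, i))
    st <- cpp_spike_times_base_noise(as.numeric(mn_parameters(pool, i)),
                                     common, nzc, ratio, dt)
    st <- st[st > transient]
    rates[i] <- 1000 * length(st) / (duration - transient)
  }
  list(fraction = mean(rates >= rate_min), n_firing = sum(rates >= rate_min),
       rates = rates)
}

#' Run the full pool-by-activation-level reflex study
#'
#' For each activation level: draws a stimulus train, builds the shared
#' common input (mean drive + band-pass noise) and the EPSC stimulus
#' component, then for every neuron adds its independent noise, integrates
#' the membrane model, computes discharge statistics with the inclusion
#' filter, and fits the PSF- and PSTH-cusum reflex estimates.
#'
#' @param pool an [mn_pool()].
#' @param drives mean drives in nA, one per activation level (defaults to
#'   the seven levels 4, 6, ..., 16 nA).
#' @param n_stim stimuli per level (default 200).
#' @param seed integer master seed; every random stream derives from
#'   (seed, level, neuron).
#' @param bin_width cusum bin width in ms.
#' @param dt integration step in ms.
#' @param epsc_gain,epsc_tau EPSC peak (nA) and time constant (ms).
#' @param stim_mean_isi,stim_sd_isi inter-stimulus interval mean/SD in ms.
#' @param neurons optional subset of neuron indices to simulate.
#' @param progress print one line per level.
#' @return An object of class `pool_study`: a data frame with one row per
#'   (neuron, level) holding discharge statistics, inclusion flag, and the
#'   PSF/PSTH amplitude estimates with significance flags.
#' @export
run_pool_study <- function(pool, drives = seq(4, 16, by = 2), n_stim = 200,
                           seed = 1L, bin_width = 1, dt = 0.05,
                           epsc_gain = 6, epsc_tau = 1,
                           stim_mean_isi = 1000, stim_sd_isi = 100,
                           neurons = NULL, progress = FALSE) {
  stopifnot(inherits(pool, "mn_pool"))
  if (is.null(neurons)) neurons <- seq_len(nrow(pool))
  rows <- vector("list", length(drives) * length(neurons))
  ri <- 0L
  for (lev in seq_along(drives)) {
    drive <- drives[lev]
    stim <- stimulus_train(n_stim, mean_isi = stim_mean_isi,
                           sd_isi = stim_sd_isi,
                           seed = .sub_seed(seed, lev, -1L))
    duration <- (ceiling((max(as.numeric(stim)) + 300) / dt)) * dt
    cfg <- input_config(mean_drive = drive, duration = duration, dt = dt,
                        seed = .sub_seed(seed, lev))
    base <- as.numeric(common_input(cfg)) +
      as.numeric(stimulus_current(stim, round(duration / dt), dt,
                                  gain = epsc_gain, tau = epsc_tau))
    if (progress)
      cat(sprintf("level %d (%.0f nA): %d neurons, %d stimuli\n",
                  lev, drive, length(neurons), n_stim))
    ratio <- round(cfg$noise_dt / dt)
    for (i in neurons) {
      nzc <- .indep_noise_coarse(cfg, .sub_seed(seed, lev, i))
      st <- cpp_spike_times_base_noise(as.numeric(mn_parameters(pool, i)),
                                       base, nzc, ratio, dt)
      train <- spike_train(st, duration, source = "simulated")
      dr <- background_dr(train, stim)
      cv <- tryCatch(cov_isi(train, stim), error = function(e) NA_real_)
      inc <- if (is.na(cv)) FALSE else include_unit(dr, cv, "simulated")
      psf <- psth <- NULL
      if (inc) {
        psf <- reflex_fit(train, stim, method = "psf", mode = "simulated",
                          bin_width = bin_width)$estimate
        psth <- reflex_fit(train, stim, method = "psth", mode = "simulated",
                           bin_width = bin_width)$estimate
      }
      g <- function(e, f) if (is.null(e)) NA_real_ else e[[f]]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        level = lev, drive = drive, neuron = i,
        size_scale = pool$size_scale[i], r_input = pool$r_input[i],
        rheobase = pool$rheobase[i],
        dr = dr, cov_isi = cv, included = inc,
        psf_amp = g(psf, "amplitude_norm"),
        psf_sig = if (is.null(psf)) FALSE else isTRUE(psf$significant),
        psf_onset = g(psf, "onset"), psf_dur = g(psf, "duration"),
        psth_amp = g(psth, "amplitude_norm"),
        psth_sig = if (is.null(psth)) FALSE else isTRUE(psth$significant),
        psth_onset = g(psth, "onset"), psth_dur = g(psth, "duration"))
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  attr(out, "n_stim") <- n_stim
  attr(out, "seed") <- seed
  attr(out, "drives") <- drives
  class(out) <- c("pool_study", "data.frame")
  out
}

#' @export
print.pool_study <- function(x, ...) {
  cat(sprintf("Pool study: %d neurons x %d levels, %d stimuli per level\n",
              length(unique(x$neuron)), length(unique(x$level)),
              attr(x, "n_stim")))
  print(study_counts(x))
  invisible(x)
}

#' Included and significant unit counts per activation level
#'
#' @param study a [run_pool_study()] result.
#' @return A data frame with one row per level: units passing the
#'   inclusion filter and units with significant PSTH / PSF reflexes.
#' @export
study_counts <- function(study) {
  lv <- sort(unique(study$level))
  data.frame(
    level = lv,
    included = vapply(lv, function(l)
      sum(study$included[study$level == l]), numeric(1)),
    psth_significant = vapply(lv, function(l)
      sum(study$psth_sig[study$level == l]), numeric(1)),
    psf_significant = vapply(lv, function(l)
      sum(study$psf_sig[study$level == l]), numeric(1)))
}

#' Write a study results table to CSV
#' @param study a [run_pool_study()] result.
#' @param file output path.
#' @export
write_study <- function(study, file) {
  write.csv(as.data.frame(study), file, row.names = FALSE)
  invisible(file)
}
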