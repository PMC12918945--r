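# Synaptic input: common drive with band-pass noise, independent low-pass
# noise, EPSC stimulus train, and their assembly into one soma current.
#
# Noise components are band-limited below 100 Hz, so they are synthesized
# on a coarser 1 ms grid (1 kHz sampling), zero-phase filtered and rescaled
# there, and linearly interpolated onto the integration grid.  This keeps
# the Butterworth designs well conditioned (the pass bands are a sizeable
# fraction of the 500 Hz Nyquist frequency) and makes long pool runs cheap.

#' Input configuration for one activation level
#'
#' Collects every constant of the three-component input current: the mean
#' common drive, the band-pass filtered common noise, the low-pass filtered
#' independent noise and the sampling grids.
#'
#' @param mean_drive mean common drive in nA (the seven default activation
#'   levels use 4, 6, 8, 10, 12, 14, 16 nA).
#' @param duration trace length in ms.
#' @param dt integration-grid step in ms.
#' @param noise_dt synthesis grid for the band-limited noise in ms.
#' @param common_band common-noise pass band in Hz.
#' @param common_order Butterworth order of the common band-pass filter.
#' @param common_sd_frac common-noise standard deviation as a fraction of
#'   the mean drive.
#' @param indep_cutoff independent-noise low-pass cutoff in Hz.
#' @param indep_order Butterworth order of the independent low-pass filter.
#' @param indep_share share of the total noise variance carried by the
#'   independent component.
#' @param seed integer seed of the common-noise stream; independent streams
#'   derive from it per neuron.
#' @return A list of class `input_config`.
#' @export
input_config <- function(mean_drive, duration, dt = 0.05, noise_dt = 1,
                         common_band = c(15, 35), common_order = 4,
                         common_sd_frac = 0.2,
                         indep_cutoff = 100, indep_order = 2,
                         indep_share = 0.2, seed = 1L) {
  if (mean_drive < 0) stop("'mean_drive' must be non-negative")
  if (duration <= 0) stop("'duration' must be positive")
  nyq <- 500 / noise_dt
  if (!(common_band[1] > 0 && common_band[1] < common_band[2] &&
        common_band[2] < nyq))
    stop("common-noise band must satisfy 0 < low < high < Nyquist")
  if (indep_cutoff <= 0 || indep_cutoff >= nyq)
    stop("independent-noise cutoff must lie below the Nyquist frequency")
  if (common_sd_frac < 0 || common_sd_frac > 1 ||
      indep_share < 0 || indep_share >= 1)
    stop("noise fractions must lie in [0, 1)")
  structure(list(mean_drive = mean_drive, duration = duration, dt = dt,
                 noise_dt = noise_dt, common_band = common_band,
                 common_order = common_order,
                 common_sd_frac = common_sd_frac,
                 indep_cutoff = indep_cutoff, indep_order = indep_order,
                 indep_share = indep_share, seed = as.integer(seed)),
            class = "input_config")
}

#' A sampled current trace
#'
#' Thin wrapper around a numeric vector of nA values on a fixed time grid,
#' carrying `dt` and a component label.
#' @param values current samples in nA.
#' @param dt sample step in ms.
#' @param component label: "common", "independent", "stimulus" or "total".
#' @export
current_trace <- function(values, dt, component = "total") {
  structure(as.numeric(values), dt = dt, component = component,
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace (%s): %.1f ms at dt = %g ms, mean %.3f nA, sd %.3f nA\n",
              attr(x, "component"), length(x) * attr(x, "dt"),
              attr(x, "dt"), mean(x), sd(x)))
  invisible(x)
}

# zero-mean, unit-SD band-limited Gaussian noise on the synthesis grid,
# zero-phase (forward-backward) Butterworth filtered, edge-padded
.filtered_noise <- function(n_samples, noise_dt, type, freq, order) {
  pad <- ceiling(2000 / noise_dt)                 # 2 s padding per edge
  x <- rnorm(n_samples + 2 * pad)
  w <- freq / (500 / noise_dt)                    # normalized to Nyquist
  bf <- signal::butter(order, w, type = type)
  y <- signal::filtfilt(bf, x)
  y <- y[(pad + 1):(pad + n_samples)]
  y / sd(y)
}

# interpolate a coarse-grid series onto the integration grid
.to_fine_grid <- function(coarse, noise_dt, dt, n_fine) {
  t_coarse <- (seq_along(coarse) - 1) * noise_dt
  t_fine <- (seq_len(n_fine) - 1) * dt
  approx(t_coarse, coarse, xout = t_fine, rule = 2)$y
}

#' Common input: mean drive plus band-pass filtered Gaussian noise
#'
#' The common component is a constant mean drive plus zero-mean Gaussian
#' noise band-pass filtered to the configured band (default 15-35 Hz,
#' fourth-order Butterworth, applied forward-backward) and rescaled after
#' filtering so its standard deviation is the configured fraction of the
#' mean (default 20 %).  The same realization is shared by every neuron of
#' the pool within one activation level.
#'
#' @param cfg an [input_config()].
#' @return A [current_trace()] with component label "common".
#' @export
common_input <- function(cfg) {
  stopifnot(inherits(cfg, "input_config"))
  n_fine <- round(cfg$duration / cfg$dt)
  if (cfg$common_sd_frac == 0 || cfg$mean_drive == 0)
    return(current_trace(rep(cfg$mean_drive, n_fine), cfg$dt, "common"))
  n_coarse <- ceiling(cfg$duration / cfg$noise_dt) + 1
  set.seed(cfg$seed)
  z <- .filtered_noise(n_coarse, cfg$noise_dt, "pass", cfg$common_band,
                       cfg$common_order)
  noise <- .to_fine_grid(z, cfg$noise_dt, cfg$dt, n_fine)
  current_trace(cfg$mean_drive + cfg$common_sd_frac * cfg$mean_drive * noise,
                cfg$dt, "common")
}

#' Independent input noise of one neuron
#'
#' Zero-mean Gaussian noise low-pass filtered below the configured cutoff
#' (default 100 Hz, second-order Butterworth, forward-backward) and scaled
#' so that the independent component carries the configured share of the
#' total noise variance (default 20 %): with common noise SD `f * mu`, the
#' independent SD is `f * mu * sqrt(share / (1 - share))`.  Each neuron
#' uses its own stream, uncorrelated across neurons.
#'
#' @param cfg an [input_config()].
#' @param neuron_seed integer seed of this neuron's stream.
#' @return A [current_trace()] with component label "independent".
#' @export
independent_noise <- function(cfg, neuron_seed) {
  stopifnot(inherits(cfg, "input_config"))
  n_fine <- round(cfg$duration / cfg$dt)
  sd_target <- cfg$common_sd_frac * cfg$mean_drive *
    sqrt(cfg$indep_share / (1 - cfg$indep_share))
  if (sd_target == 0)
    return(current_trace(numeric(n_fine), cfg$dt, "independent"))
  n_coarse <- ceiling(cfg$duration / cfg$noise_dt) + 1
  set.seed(as.integer(neuron_seed))
  z <- .filtered_noise(n_coarse, cfg$noise_dt, "low", cfg$indep_cutoff,
                       cfg$indep_order)
  noise <- .to_fine_grid(z, cfg$noise_dt, cfg$dt, n_fine)
  current_trace(sd_target * noise, cfg$dt, "independent")
}

# coarse-grid independent-noise trace (already scaled to its target SD),
# consumed by the pool fast path which interpolates it during integration
.indep_noise_coarse <- function(cfg, neuron_seed) {
  n_coarse <- ceiling(cfg$duration / cfg$noise_dt) + 2
  sd_target <- cfg$common_sd_frac * cfg$mean_drive *
    sqrt(cfg$indep_share / (1 - cfg$indep_share))
  if (sd_target == 0) return(numeric(n_coarse))
  set.seed(as.integer(neuron_seed))
  sd_target * .filtered_noise(n_coarse, cfg$noise_dt, "low",
                              cfg$indep_cutoff, cfg$indep_order)
}

#' EPSC waveform of the reflex stimulus
#'
#' The excitatory postsynaptic current evoked by one stimulus,
#' `gain * (t/tau) * exp(1 - t/tau)` for `0 <= t <= support` and zero
#' afterwards.  The peak equals `gain` at `t = tau`.
#'
#' @param t time since stimulus onset in ms (vectorized, must be >= 0).
#' @param gain peak current in nA (default 6).
#' @param tau rise time constant in ms (default 1).
#' @param support waveform support in ms (default 40); the waveform is
#'   truncated to zero beyond it (it has decayed to ~5e-15 of the peak
#'   there, so the truncation is numerically immaterial).
#' @return EPSC current in nA.
#' @examples
#' epsc_waveform(1)   # peak: 6 nA
#' @export
epsc_waveform <- function(t, gain = 6, tau = 1, support = 40) {
  if (any(t < 0)) stop("'t' must be non-negative")
  out <- gain * (t / tau) * exp(1 - t / tau)
  out[t > support] <- 0
  out
}

#' Stimulus train with Gaussian inter-stimulus intervals
#'
#' Onset times of the reflex stimuli: `n_stim` onsets separated by
#' normally distributed intervals (default 1000 +/- 100 ms), truncated from
#' below so that intervals can never overlap the EPSC support.
#'
#' @param n_stim number of stimuli (default 200).
#' @param mean_isi,sd_isi mean and SD of the inter-stimulus interval (ms).
#' @param min_isi lower truncation bound of the interval (ms, default 200).
#' @param start time of the first stimulus (ms).
#' @param seed integer seed.
#' @return An object of class `stimulus_train`: numeric onset times in ms.
#' @export
stimulus_train <- function(n_stim = 200, mean_isi = 1000, sd_isi = 100,
                           min_isi = 200, start = 1000, seed = 1L) {
  if (n_stim < 1) stop("'n_stim' must be at least 1")
  set.seed(as.integer(seed))
  isi <- if (n_stim > 1) pmax(rnorm(n_stim - 1, mean_isi, sd_isi), min_isi)
         else numeric(0)
  onsets <- start + c(0, cumsum(isi))
  structure(onsets, class = "stimulus_train", mean_isi = mean_isi,
            sd_isi = sd_isi)
}

#' @export
print.stimulus_train <- function(x, ...) {
  isi <- diff(unclass(x))
  cat(sprintf("Stimulus train: %d onsets", length(x)))
  if (length(isi))
    cat(sprintf(", ISI %.0f +/- %.0f ms", mean(isi), sd(isi)))
  cat("\n")
  invisible(x)
}

#' Stimulus-train current component
#'
#' Sum of EPSC waveforms placed at every stimulus onset, sampled on the
#' integration grid.
#'
#' @param stimuli a [stimulus_train()] or numeric onset times in ms.
#' @param n_samples length of the trace.
#' @param dt sample step in ms.
#' @inheritParams epsc_waveform
#' @return A [current_trace()] with component label "stimulus".
#' @export
stimulus_current <- function(stimuli, n_samples, dt = 0.05, gain = 6,
                             tau = 1, support = 40) {
  vals <- numeric(n_samples)
  wave_t <- seq(0, support, by = dt)
  wave <- epsc_waveform(wave_t, gain, tau, support)
  for (on in as.numeric(stimuli)) {
    i0 <- floor(on / dt) + 1
    if (i0 > n_samples) next
    idx <- i0:min(n_samples, i0 + length(wave) - 1)
    vals[idx] <- vals[idx] + wave[seq_along(idx)]
  }
  current_trace(vals, dt, "stimulus")
}

#' Assemble the total input current
#'
#' Exact sample-wise sum of the component traces; all components must share
#' the same grid.
#'
#' @param ... [current_trace()] objects (or numeric vectors of equal
#'   length, assumed on the same grid).
#' @param dt sample step in ms, required if no argument carries one.
#' @return A [current_trace()] with component label "total".
#' @export
assemble_input <- function(..., dt = NULL) {
  comps <- list(...)
  if (!length(comps)) stop("no components given")
  n <- unique(vapply(comps, length, integer(1)))
  if (length(n) != 1) stop("component grids do not match (unequal lengths)")
  dts <- unlist(lapply(comps, attr, "dt"))
  if (length(dts)) {
    if (max(dts) - min(dts) > 1e-12) stop("component grids do not match (dt)")
    dt <- dts[1]
  }
  if (is.null(dt)) stop("no dt available")
  total <- Reduce(`+`, lapply(comps, as.numeric))
  current_trace(total, dt, "total")
}
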