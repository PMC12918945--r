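# Surrogate spike trains with controlled discharge statistics and known
# injected reflex responses: the ground-truth oracle for the peristimulus
# estimators, independent of the biophysical simulator.

#' Gaussian-renewal surrogate spike train
#'
#' Renewal process with Gaussian interspike intervals targeting a given
#' discharge rate and ISI coefficient of variation.  Intervals are
#' redrawn while below 10 % of the mean, so they stay positive.
#'
#' @param dr target discharge rate in Hz (> 0).
#' @param cov target ISI coefficient of variation in percent.
#' @param duration train duration in ms.
#' @param seed integer seed.
#' @param min_isi_frac lower truncation of the ISI as a fraction of its
#'   mean (default 0.1).
#' @return A [spike_train()] with source "surrogate".
#' @export
surrogate_train <- function(dr, cov, duration, seed = 1L,
                            min_isi_frac = 0.1) {
  if (dr <= 0) stop("'dr' must be positive")
  if (cov < 0) stop("'cov' must be non-negative")
  mean_isi <- 1000 / dr
  sd_isi <- cov / 100 * mean_isi
  if (sd_isi > 0 && mean_isi * min_isi_frac > mean_isi + 6 * sd_isi)
    stop("infeasible DR/CoV target")
  set.seed(as.integer(seed))
  n_guess <- ceiling(duration / mean_isi * 1.3) + 10
  times <- numeric(0)
  t <- runif(1, 0, mean_isi)                      # random phase at t = 0
  repeat {
    isi <- rnorm(n_guess, mean_isi, sd_isi)
    bad <- isi < min_isi_frac * mean_isi
    while (any(bad)) {
      isi[bad] <- rnorm(sum(bad), mean_isi, sd_isi)
      bad <- isi < min_isi_frac * mean_isi
    }
    new <- t + cumsum(isi)
    times <- c(times, new)
    t <- times[length(times)]
    if (t > duration) break
  }
  spike_train(times[times <= duration], duration, source = "surrogate")
}

#' Inject a known reflex response into a spike train
#'
#' Two modes: `"extra"` inserts one additional discharge at
#' `onset + latency` with the given probability per stimulus and records
#' exactly which stimuli received one (the oracle for extra-count per
#' stimulation); `"reset"` advances the first natural discharge after the
#' stimulus to `onset + latency`, modelling a phase reset of the
#' oscillator.  An insertion colliding with an existing spike within 1 ms
#' is jittered by +0.5 ms.
#'
#' @param train a [spike_train()].
#' @param stimuli a [stimulus_train()] or numeric onsets in ms.
#' @param mode "extra" or "reset".
#' @param prob per-stimulus response probability in `[0, 1]`.
#' @param latency response latency after stimulus onset in ms.
#' @param seed integer seed for the per-stimulus Bernoulli draws.
#' @return A list with `train` (the modified [spike_train()]), `injected`
#'   (logical per stimulus) and `n_injected`.
#' @export
inject_reflex <- function(train, stimuli, mode = c("extra", "reset"),
                          prob = 1, latency = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (prob < 0 || prob > 1) stop("'prob' must lie in [0, 1]")
  on <- as.numeric(stimuli)
  tt <- as.numeric(train)
  duration <- attr(train, "duration")
  set.seed(as.integer(seed))
  injected <- runif(length(on)) < prob
  for (k in which(injected)) {
    t_new <- on[k] + latency
    if (mode == "extra") {
      if (any(abs(tt - t_new) < 1)) t_new <- t_new + 0.5
      tt <- sort(c(tt, t_new))
    } else {
      nxt <- which(tt > on[k])[1]
      if (is.na(nxt)) { injected[k] <- FALSE; next }
      if (tt[nxt] <= t_new) { injected[k] <- FALSE; next }
      tt[nxt] <- t_new
    }
  }
  tt <- tt[tt <= duration]
  tt <- tt[!duplicated(tt)]
  list(train = spike_train(tt, duration, source = "surrogate"),
       injected = injected, n_injected = sum(injected))
}
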