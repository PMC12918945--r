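# Single-cell simulation: membrane integration, rheobase, f-I curve.

#' Integrate the membrane dynamics of one motor neuron
#'
#' Runs the two-compartment model under an arbitrary injected soma current.
#' Gating variables are advanced with exact (Rush-Larsen) exponential
#' updates and the membrane potentials with a semi-implicit Euler step.
#' The integration is fully deterministic: all stochasticity lives in the
#' input current.
#'
#' @param params an `mn_params` vector from [mn_parameters()], or any named
#'   vector with the same layout.
#' @param current injected soma current: a [current_trace()] object or a
#'   plain numeric vector in nA sampled at `dt`.
#' @param dt integration step in ms (must be <= 0.1; default 0.05).
#' @param record_voltage keep the full soma voltage trace (switch off for
#'   long pool runs, where only spike times are needed).
#' @return An object of class `membrane_trace`: list with `dt`, `n`,
#'   `spike_times` (ms, upward crossings of the detection level with a 1 ms
#'   lockout, linearly interpolated within the step) and, if requested,
#'   the soma voltage `v` (mV).
#' @examples
#' p <- mn_parameters(mn_pool(10), 1)
#' tr <- simulate_mn(p, rep(3, 20000))   # 1 s of constant 3 nA
#' length(tr$spike_times)
#' @export
simulate_mn <- function(params, current, dt = 0.05, record_voltage = TRUE) {
  vals <- if (inherits(current, "current_trace")) {
    if (!isTRUE(all.equal(attr(current, "dt"), dt)))
      stop("current trace dt does not match integration dt")
    as.numeric(current)
  } else as.numeric(current)
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms")
  res <- cpp_simulate_mn(as.numeric(params)[1:22], vals, dt, record_voltage)
  out <- list(dt = dt, n = length(vals), spike_times = res$spike_times,
              v = if (record_voltage) res$v else NULL)
  class(out) <- "membrane_trace"
  out
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("Membrane trace: %.1f ms at dt = %g ms, %d spikes\n",
              x$n * x$dt, x$dt, length(x$spike_times)))
  invisible(x)
}

#' @export
plot.membrane_trace <- function(x, ...) {
  if (is.null(x$v)) stop("voltage was not recorded")
  t <- seq_len(x$n) * x$dt
  plot(t, x$v, type = "l", xlab = "time (ms)", ylab = "soma potential (mV)",
       ...)
  invisible(x)
}

#' Mean firing rate under a constant current
#' @noRd
.tonic_rate <- function(params, current_nA, duration = 6000, transient = 2000,
                        dt = 0.05) {
  st <- cpp_spike_times(as.numeric(params)[1:22],
                        rep(current_nA, round(duration / dt)), dt)
  st <- st[st > transient]
  if (length(st) < 2) return(0)
  1000 * (length(st) - 1) / (st[length(st)] - st[1])
}

#' Rheobase of a motor neuron
#'
#' Bisection estimate of the minimal constant soma current that produces
#' sustained firing (at least two spikes after a discarded transient).
#'
#' @param params an `mn_params` vector.
#' @param tolerance bisection tolerance in nA.
#' @param bracket initial search bracket in nA; the upper end is doubled
#'   until it produces firing.
#' @param duration,transient simulation length and discarded transient (ms).
#' @return Rheobase in nA.
#' @export
rheobase_estimate <- function(params, tolerance = 0.005,
                              bracket = c(0.05, 8),
                              duration = 4000, transient = 1500) {
  if (tolerance <= 0) stop("'tolerance' must be positive")
  lo <- bracket[1]; hi <- bracket[2]
  fires <- function(I) .tonic_rate(params, I, duration, transient) > 0
  if (fires(lo))
    stop("lower bracket already fires; decrease bracket[1]")
  tries <- 0
  while (!fires(hi)) {
    hi <- hi * 2; tries <- tries + 1
    if (tries > 12) stop("no firing up to ", hi, " nA: bracket failure")
  }
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Current-frequency (f-I) relation
#'
#' Simulates the neuron at each constant current and returns the mean
#' discharge rate after a discarded transient.
#'
#' @param params an `mn_params` vector.
#' @param currents constant current values in nA, sorted ascending.
#' @param duration simulated time per current (ms), at least 5000 after the
#'   transient for a stable rate estimate.
#' @param transient discarded initial interval (ms).
#' @param dt integration step (ms).
#' @return A data frame with columns `current` (nA) and `rate` (Hz).
#' @export
f_i_curve <- function(params, currents, duration = 7000, transient = 2000,
                      dt = 0.05) {
  if (is.unsorted(currents)) stop("'currents' must be sorted ascending")
  rate <- vapply(currents, function(I)
    .tonic_rate(params, I, duration + transient, transient, dt), numeric(1))
  data.frame(current = currents, rate = rate)
}
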