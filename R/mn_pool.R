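# Canonical two-compartment motor neuron and the size-scaled pool.
#
# All neurons in the pool are size-scaled copies of one canonical cell:
# every conductance and capacitance is multiplied by the same size factor
# s, so a neuron with size s driven by a current I behaves exactly like the
# canonical cell driven by I/s.  Input resistance is proportional to 1/s
# and rheobase to s, which makes the exponential membrane-resistance
# profile equivalent to an exponential rheobase profile across the pool.

# canonical parameter vector; units: nF, uS, mV, ms^-1.
# Index layout must match src/mn_model.cpp.
.mn_canonical <- c(
  Cs = 1.0, Cd = 2.0,           # compartment capacitances (nF)
  gls = 0.09, gld = 0.055,      # soma/dendrite leak (uS)
  gc = 0.1,                     # soma-dendrite coupling (uS)
  gNa = 30, gKf = 4, gKs = 20,  # maximal conductances (uS)
  ENa = 50, EK = -80, EL = -70, # reversal potentials (mV)
  Vgate = -59.7,                # gating switch threshold (mV)
  am = 22, bm = 13,             # Na activation rates (ms^-1)
  ah = 0.5, bh = 4,             # Na inactivation rates
  an = 1.5, bn = 0.1,           # fast K rates
  aq = 0.8, bq = 0.05,          # slow K (AHP) rates
  Vdetect = 0,                  # spike detection level (mV)
  lockout = 1                   # detection refractory lockout (ms)
)

# Calibration constants for the default pool (see the methods vignette):
# .RHEO0      canonical rheobase (nA), bisection at tolerance 1e-4;
# .POOL_K     exponent of the rheobase/resistance profile, chosen so the
#             drive ratio between the 44.5 % and 98.5 % recruitment anchors
#             is 16/4 = 4: k = log(4) * 199 / 108;
# .S_ANCHOR   size factor of pool index 89 in a 200-cell pool, chosen so
#             that the cell sits at the drive where the canonical cell's
#             noise-on discharge rate crosses the 7 Hz sustained-firing
#             bound at a 4 nA mean drive.
.RHEO0 <- 1.29226
.POOL_K <- log(4) * 199 / 108
.S_ANCHOR <- 4 / 1.183

#' Canonical input resistance (MOhm) seen from the soma
#' @noRd
.r_input_canonical <- function(p = .mn_canonical) {
  g_in <- p[["gls"]] + p[["gc"]] * p[["gld"]] / (p[["gc"]] + p[["gld"]])
  1 / g_in
}

#' Build a calibrated motor neuron pool
#'
#' Constructs a pool of `n` two-compartment motor neurons ordered by size:
#' index 1 is the smallest cell (highest input resistance, lowest
#' rheobase).  The soma input resistance decreases exponentially with the
#' index, `R(i) = R(1) * exp(-k * (i-1)/(n-1))`, and rheobase increases by
#' the same exponential factor.  The default exponent and anchor are
#' calibrated so that, in a 200-cell pool under the default noise
#' configuration, about 44.5 % of the cells fire sustainedly at a 4 nA
#' mean drive and about 98.5 % at 16 nA.
#'
#' @param n number of motor neurons (default 200, the approximate number of
#'   motor neurons innervating the human tibialis anterior).
#' @param k decay exponent of the input-resistance profile.
#' @param composition multiplier applied to `k` to generate pools with a
#'   biased size distribution while keeping the smallest cell fixed:
#'   values < 1 compress the profile towards high resistances
#'   (proportionally more small cells), values > 1 stretch it towards low
#'   resistances (proportionally more large cells).
#' @param s_anchor size factor assigned to the 44.5 % anchor index
#'   (index 89 of 200); the remaining cells follow the exponential profile
#'   through this anchor.
#' @param canonical named vector of canonical-cell constants (advanced use;
#'   defaults to the calibrated cell, `reflexpool:::.mn_canonical`).
#'
#' @return An object of class `mn_pool`: a data frame with one row per
#'   neuron (`index`, `size_scale`, `r_input` in MOhm, `rheobase` in nA)
#'   and the canonical parameters attached as attributes.
#' @examples
#' pool <- mn_pool(10)
#' pool$rheobase
#' @export
mn_pool <- function(n = 200, k = .POOL_K, composition = 1,
                    s_anchor = .S_ANCHOR, canonical = .mn_canonical) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (!is.numeric(k) || k <= 0 || !is.finite(k))
    stop("'k' must be a positive finite exponent")
  if (!is.numeric(composition) || composition <= 0)
    stop("'composition' must be a positive multiplier")
  kk <- k * composition
  # anchor the profile at the smallest cell so that pools with different
  # compositions share their low-threshold end
  s1 <- s_anchor * exp(-k * 88 / 199)
  frac <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  s <- s1 * exp(kk * frac)
  pool <- data.frame(
    index = seq_len(n),
    size_scale = s,
    r_input = .r_input_canonical(canonical) / s,
    rheobase = .RHEO0 * s
  )
  class(pool) <- c("mn_pool", "data.frame")
  attr(pool, "canonical") <- canonical
  attr(pool, "k") <- kk
  attr(pool, "composition") <- composition
  pool
}

#' Per-neuron model parameters
#'
#' Returns the full electrical parameter vector of neuron `i` of a pool:
#' the canonical cell with all conductances and capacitances multiplied by
#' the neuron's size factor.
#'
#' @param pool an [mn_pool()] object.
#' @param i neuron index.
#' @return A named numeric vector of class `mn_params` with attributes
#'   `index` and `rheobase`.
#' @export
mn_parameters <- function(pool, i) {
  stopifnot(inherits(pool, "mn_pool"))
  if (i < 1 || i > nrow(pool)) stop("neuron index out of range")
  s <- pool$size_scale[i]
  p <- attr(pool, "canonical")
  if (is.null(p)) p <- .mn_canonical
  scaled <- c("Cs", "Cd", "gls", "gld", "gc", "gNa", "gKf", "gKs")
  p[scaled] <- p[scaled] * s
  structure(p, class = "mn_params", index = pool$index[i],
            size_scale = s, rheobase = pool$rheobase[i])
}

#' @export
print.mn_pool <- function(x, ...) {
  cat(sprintf("Motor neuron pool: %d cells\n", nrow(x)))
  cat(sprintf("  input resistance: %.2f .. %.2f MOhm (exponential, k = %.3f)\n",
              max(x$r_input), min(x$r_input), attr(x, "k")))
  cat(sprintf("  rheobase: %.2f .. %.2f nA\n",
              min(x$rheobase), max(x$rheobase)))
  invisible(x)
}

#' @export
summary.mn_pool <- function(object, drives = seq(4, 16, by = 2), ...) {
  rec <- vapply(drives, function(d) sum(object$rheobase <= d), integer(1))
  out <- list(n = nrow(object), k = attr(object, "k"),
              r_input = range(object$r_input),
              rheobase = range(object$rheobase),
              drives = drives, recruited = rec)
  class(out) <- "summary.mn_pool"
  out
}

#' @export
print.summary.mn_pool <- function(x, ...) {
  cat(sprintf("Motor neuron pool: %d cells, profile exponent %.3f\n",
              x$n, x$k))
  cat(sprintf("  input resistance %.2f .. %.2f MOhm, rheobase %.2f .. %.2f nA\n",
              x$r_input[2], x$r_input[1], x$rheobase[1], x$rheobase[2]))
  cat("  cells with rheobase at or below each mean drive:\n")
  for (j in seq_along(x$drives))
    cat(sprintf("    %5.1f nA : %4d (%.1f%%)\n", x$drives[j], x$recruited[j],
                100 * x$recruited[j] / x$n))
  invisible(x)
}

#' @export
plot.mn_pool <- function(x, ...) {
  plot(x$index, x$r_input, type = "l", xlab = "neuron index (size order)",
       ylab = "input resistance (MOhm)", main = "Pool size profile", ...)
  invisible(x)
}
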