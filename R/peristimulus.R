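# Peristimulus analysis: PSTH / PSF construction, cusum, error-box
# significance and the automated reflex detector.  reflex_fit() is the
# central estimator; it returns a classed object with print, summary,
# coef, plot and residuals methods.

#' Peristimulus data (PSTH or PSF)
#'
#' Bins spikes in a fixed window around every stimulus.  For the PSTH each
#' spike contributes a count of one to its bin; for the PSF each spike
#' contributes its instantaneous discharge rate, the reciprocal of the
#' preceding interspike interval (1000/ISI in Hz), and bins aggregate by
#' summation.  Spikes without a preceding discharge in the recording (only
#' ever the very first) are skipped in the PSF.
#'
#' @param train a [spike_train()] or numeric spike times in ms.
#' @param stimuli a [stimulus_train()] or numeric onset times in ms.
#' @param method "psth" or "psf".
#' @param window `c(pre, post)` window in ms around each stimulus; defaults
#'   to the mode-specific window, see [reflex_fit()].
#' @param bin_width bin width in ms (must tile the window exactly).
#' @return An object of class `peristimulus`: list with `method`, `edges`
#'   (bin edges in ms relative to the stimulus), `values`, `window`,
#'   `n_stim`, `bin_width`.
#' @export
peristimulus <- function(train, stimuli, method = c("psth", "psf"),
                         window = c(300, 150), bin_width = 1) {
  method <- match.arg(method)
  on <- as.numeric(stimuli)
  if (!length(on)) stop("empty stimulus list")
  pre <- window[1]; post <- window[2]
  if (pre <= 0 || post <= 0) stop("window lengths must be positive")
  nb_pre <- pre / bin_width
  nb_post <- post / bin_width
  if (abs(nb_pre - round(nb_pre)) > 1e-9 ||
      abs(nb_post - round(nb_post)) > 1e-9)
    stop("'bin_width' must divide both window lengths")
  nb_pre <- round(nb_pre); nb_post <- round(nb_post)
  nb <- nb_pre + nb_post
  edges <- seq(-pre, post, by = bin_width)

  tt <- as.numeric(train)
  values <- numeric(nb)
  if (length(tt)) {
    weight <- if (method == "psf") {
      w <- c(NA_real_, 1000 / diff(tt))  # instantaneous rate, Hz
      w
    } else rep(1, length(tt))
    for (k in seq_along(on)) {
      lo <- on[k] - pre
      hi <- on[k] + post
      sel <- which(tt >= lo & tt < hi)
      if (!length(sel)) next
      rel <- tt[sel] - on[k]
      bins <- floor((rel + pre) / bin_width) + 1
      for (j in seq_along(sel)) {
        w <- weight[sel[j]]
        if (is.na(w)) next                    # first spike of the recording
        values[bins[j]] <- values[bins[j]] + w
      }
    }
  }
  structure(list(method = method, edges = edges, values = values,
                 window = c(pre = pre, post = post), n_stim = length(on),
                 bin_width = bin_width),
            class = "peristimulus")
}

#' @export
print.peristimulus <- function(x, ...) {
  cat(sprintf("%s: %d bins of %g ms, window -%g..+%g ms, %d stimuli\n",
              toupper(x$method), length(x$values), x$bin_width,
              x$window["pre"], x$window["post"], x$n_stim))
  invisible(x)
}

#' Cumulative sum of mean-subtracted peristimulus values
#'
#' The baseline is the mean per-bin value over the pre-stimulus region;
#' the cusum at bin k is the running sum of (value - baseline).  By
#' construction the cusum over the full pre-stimulus region ends exactly
#' at zero, and a reflex response appears as a post-stimulus ramp whose
#' height measures the response magnitude.
#'
#' @param ps a [peristimulus()] object.
#' @return A list of class `cusum_trace` with `cusum`, `baseline`,
#'   `error_box` (the maximum absolute pre-stimulus cusum deflection from
#'   zero), `pre_idx`, `post_idx` and the parent data.
#' @export
ps_cusum <- function(ps) {
  stopifnot(inherits(ps, "peristimulus"))
  nb_pre <- round(ps$window["pre"] / ps$bin_width)
  if (nb_pre < 1) stop("pre-stimulus region is empty")
  pre_idx <- seq_len(nb_pre)
  post_idx <- seq(nb_pre + 1, length(ps$values))
  baseline <- mean(ps$values[pre_idx])
  cs <- cumsum(ps$values - baseline)
  structure(list(cusum = cs, baseline = baseline,
                 error_box = max(abs(cs[pre_idx])),
                 pre_idx = pre_idx, post_idx = post_idx, ps = ps),
            class = "cusum_trace")
}

#' Error-box significance threshold
#'
#' The significance band equals 100 % of the maximum pre-stimulus cusum
#' deflection from zero.  An excitatory response is significant only if
#' the post-stimulus cusum strictly exceeds the threshold.
#'
#' @param ct a `cusum_trace` from [ps_cusum()].
#' @return The threshold (counts or Hz).
#' @export
error_box <- function(ct) {
  stopifnot(inherits(ct, "cusum_trace"))
  ct$error_box
}

# automated forward-difference detector on a cusum trace; returns the
# estimate list shared by reflex_fit()
.detect_reflex <- function(ct, max_onset = 15) {
  ps <- ct$ps
  bw <- ps$bin_width
  dev <- ps$values - ct$baseline
  slope_thr <- max(abs(dev[ct$pre_idx]))
  # bin start times of the post-stimulus bins
  post_start <- ps$edges[ct$post_idx]
  qual <- dev[ct$post_idx] > slope_thr
  sig_box <- any(ct$cusum[ct$post_idx] > ct$error_box)

  null_est <- list(onset = NA_real_, end = NA_real_, latency = NA_real_,
                   duration = NA_real_, amplitude = 0,
                   amplitude_norm = 0, significant = FALSE,
                   slope_threshold = slope_thr, error_box = ct$error_box)
  if (!any(qual)) return(null_est)

  r <- rle(qual)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  runs <- which(r$values)
  if (!is.null(max_onset)) {
    ok <- post_start[run_start[runs]] <= max_onset
    runs <- runs[ok]
  }
  if (!length(runs)) return(null_est)
  run <- runs[1]                                  # earliest qualifying run
  i_first <- ct$post_idx[run_start[run]]          # absolute bin indices
  i_last <- ct$post_idx[run_end[run]]

  onset <- ps$edges[i_first]                      # start of first reflex bin
  end <- ps$edges[i_last + 1]                     # end of last reflex bin

  # first local maximum of the cusum at or after the end of the rise
  cs <- ct$cusum
  tp <- length(cs)
  for (j in i_last:(length(cs) - 1)) {
    if (cs[j] >= cs[j + 1]) { tp <- j; break }
  }
  amplitude <- cs[tp] - cs[i_first - 1]
  list(onset = onset, end = end, latency = onset, duration = end - onset,
       amplitude = amplitude, amplitude_norm = amplitude / ps$n_stim,
       significant = sig_box,
       slope_threshold = slope_thr, error_box = ct$error_box)
}

#' Fit a reflex-amplitude estimate to one unit
#'
#' The central estimator.  Builds the peristimulus data (PSF or PSTH) of
#' one unit, its cusum and error box, and runs the automated
#' forward-difference detector: the slope threshold is the largest
#' absolute pre-stimulus bin deviation; contiguous post-stimulus bins
#' exceeding it form the reflex rise; the amplitude is the cusum
#' difference between the reflex onset and the first turning point (local
#' maximum) at or after the end of the rise, normalized by the number of
#' stimuli.  Significance requires the post-stimulus cusum to strictly
#' exceed the error box.
#'
#' In "simulated" mode the window is 300 ms pre / 150 ms post and the
#' onset must occur within 15 ms of the stimulus (no conduction delays are
#' modeled); in "experimental" mode the window is 200 ms pre / 100 ms post
#' and no onset bound is applied (latencies include conduction delays).
#'
#' @inheritParams peristimulus
#' @param mode "simulated" or "experimental" (sets window and onset bound).
#' @param window optional override of the mode window, `c(pre, post)` ms.
#' @param max_onset optional override of the onset bound in ms
#'   (`NULL` for none).
#' @return An object of class `reflex_fit`.
#' @examples
#' st <- stimulus_train(50, seed = 2)
#' tr <- surrogate_train(dr = 10, cov = 15, duration = 52000, seed = 3)
#' inj <- inject_reflex(tr, st, prob = 1, latency = 5, seed = 4)
#' fit <- reflex_fit(inj$train, st, method = "psth")
#' coef(fit)["amplitude_norm"]   # ~1 extra count per stimulus
#' @export
reflex_fit <- function(train, stimuli, method = c("psf", "psth"),
                       mode = c("simulated", "experimental"),
                       bin_width = 1, window = NULL, max_onset = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (is.null(window))
    window <- if (mode == "simulated") c(300, 150) else c(200, 100)
  if (is.null(max_onset))
    max_onset <- if (mode == "simulated") 15 else NULL
  ps <- peristimulus(train, stimuli, method = method, window = window,
                     bin_width = bin_width)
  ct <- ps_cusum(ps)
  est <- .detect_reflex(ct, max_onset = max_onset)
  structure(list(method = method, mode = mode, ps = ps, cusum = ct,
                 estimate = est, n_stim = ps$n_stim,
                 call = match.call()),
            class = "reflex_fit")
}

#' @export
print.reflex_fit <- function(x, ...) {
  e <- x$estimate
  unit <- if (x$method == "psf") "Hz" else "counts"
  cat(sprintf("Reflex fit (%s-cusum, %s mode, %d stimuli)\n",
              toupper(x$method), x$mode, x$n_stim))
  if (is.na(e$onset)) {
    cat("  no reflex response detected\n")
  } else {
    cat(sprintf("  onset %.1f ms, duration %.1f ms\n", e$onset, e$duration))
    cat(sprintf("  amplitude %.3f %s (%.4f %s/stimulus), %s\n",
                e$amplitude, unit, e$amplitude_norm, unit,
                if (e$significant) "significant" else "not significant"))
  }
  invisible(x)
}

#' @export
coef.reflex_fit <- function(object, ...) {
  e <- object$estimate
  c(onset = e$onset, end = e$end, latency = e$latency,
    duration = e$duration, amplitude = e$amplitude,
    amplitude_norm = e$amplitude_norm,
    significant = as.numeric(e$significant))
}

#' @export
summary.reflex_fit <- function(object, ...) {
  out <- list(coef = coef(object), method = object$method,
              mode = object$mode, n_stim = object$n_stim,
              error_box = object$estimate$error_box,
              slope_threshold = object$estimate$slope_threshold,
              baseline = object$cusum$baseline)
  class(out) <- "summary.reflex_fit"
  out
}

#' @export
print.summary.reflex_fit <- function(x, ...) {
  cat(sprintf("Reflex fit (%s-cusum, %s mode)\n", toupper(x$method), x$mode))
  cat(sprintf("  stimuli: %d, baseline %.3f per bin\n", x$n_stim, x$baseline))
  cat(sprintf("  error box %.3f, slope threshold %.3f\n",
              x$error_box, x$slope_threshold))
  print(round(x$coef, 4))
  invisible(x)
}

#' Per-bin deviations from the pre-stimulus baseline
#' @param object a [reflex_fit()] object.
#' @param ... unused.
#' @export
residuals.reflex_fit <- function(object, ...) {
  object$ps$values - object$cusum$baseline
}

#' Plot a reflex fit: cusum with error box and detected response
#' @param x a [reflex_fit()] object.
#' @param ... passed to [plot()].
#' @export
plot.reflex_fit <- function(x, ...) {
  ct <- x$cusum
  ps <- x$ps
  tt <- ps$edges[-1]                              # bin end times
  ylab <- if (x$method == "psf") "PSF cusum (Hz)" else "PSTH cusum (counts)"
  plot(tt, ct$cusum, type = "l", xlab = "time from stimulus (ms)",
       ylab = ylab, ...)
  rect(-ps$window["pre"], -ct$error_box, ps$window["post"], ct$error_box,
       border = NA, col = adjustcolor("grey", 0.4))
  abline(v = 0, lty = 3)
  e <- x$estimate
  if (!is.na(e$onset)) {
    abline(v = c(e$onset, e$end), col = "red", lty = 2)
    legend("topleft", bty = "n", legend = sprintf(
      "amp %.3f/stim%s", e$amplitude_norm,
      if (e$significant) " *" else ""))
  }
  invisible(x)
}
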