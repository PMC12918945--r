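# Population-level statistics: standardized regression, one-tailed Pearson
# correlation with a qualitative rating, amplitude dispersion per level,
# empirical cumulative distributions across pool compositions, and
# per-unit tracking across activation levels.

#' Z-score standardization
#'
#' `(x - mean(x)) / sigma_x` with the population (denominator n) standard
#' deviation, so comparisons of regression coefficients are on a common
#' scale.
#'
#' @param x numeric vector with at least two distinct values.
#' @return The standardized vector (mean 0, population SD 1).
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need at least two values")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero variance: cannot standardize")
  (x - mean(x)) / s
}

#' Linear regression of standardized reflex amplitude on discharge rate
#'
#' Ordinary least squares of the z-scored amplitudes on the background
#' discharge rate; the p-value is the two-sided t-test of the slope.
#'
#' @param dr background discharge rates (Hz).
#' @param amplitude reflex amplitudes (standardized internally).
#' @param standardize z-score the amplitudes first (default TRUE).
#' @return A list of class `amp_regression`: `slope`, `intercept`, `r2`,
#'   `p`, `residuals`, `n`.
#' @export
amplitude_regression <- function(dr, amplitude, standardize = TRUE) {
  keep <- is.finite(dr) & is.finite(amplitude)
  dr <- dr[keep]; amplitude <- amplitude[keep]
  if (length(dr) < 3) stop("need at least 3 observations")
  if (length(unique(dr)) < 2) stop("degenerate predictor")
  y <- if (standardize) zscore(amplitude) else amplitude
  fit <- lm(y ~ dr)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p = unname(sm$coefficients[2, 4]),
                 residuals = unname(fit$residuals),
                 n = length(dr)),
            class = "amp_regression")
}

#' @export
print.amp_regression <- function(x, ...) {
  cat(sprintf("slope %.4f, R^2 %.3f, p %.4g (n = %d)\n",
              x$slope, x$r2, x$p, x$n))
  invisible(x)
}

# qualitative strength bands for |rho| (conventional 0.3 / 0.5 / 0.8 cuts)
.cor_rating <- function(rho) {
  a <- abs(rho)
  if (a < 0.3) "poor" else if (a < 0.5) "fair"
  else if (a < 0.8) "moderate" else "strong"
}

#' One-tailed Pearson correlation with a qualitative rating
#'
#' Bivariate Pearson correlation tested one-tailed in the stated expected
#' direction, with the conventional qualitative bands for |rho|: poor
#' below 0.3, fair 0.3-0.5, moderate 0.5-0.8, strong at or above 0.8.
#'
#' @param x,y numeric vectors.
#' @param expected_sign "positive" or "negative": the alternative tested.
#' @return A list of class `cor_result`: `rho`, `p` (one-tailed), `n`,
#'   `rating`.
#' @export
pearson_one_tailed <- function(x, y,
                               expected_sign = c("positive", "negative")) {
  expected_sign <- match.arg(expected_sign)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  alt <- if (expected_sign == "positive") "greater" else "less"
  ct <- cor.test(x, y, method = "pearson", alternative = alt)
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
                 rating = .cor_rating(unname(ct$estimate))),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("rho %.3f (%s), one-tailed p %.4g, n %d\n",
              x$rho, x$rating, x$p, x$n))
  invisible(x)
}

#' Coefficient of variation of reflex amplitudes per activation level
#'
#' `100 * SD / mean` (population SD) of the normalized amplitudes among
#' units with a significant reflex at each level.
#'
#' @param study a [run_pool_study()] result.
#' @param method "psf" or "psth".
#' @return Named numeric vector, CoV in percent per level (NA where fewer
#'   than 2 significant units).
#' @export
amplitude_cov <- function(study, method = c("psf", "psth")) {
  method <- match.arg(method)
  amp_col <- paste0(method, "_amp")
  sig_col <- paste0(method, "_sig")
  lv <- sort(unique(study$level))
  out <- vapply(lv, function(l) {
    a <- study[[amp_col]][study$level == l & study[[sig_col]]]
    a <- a[is.finite(a)]
    if (length(a) < 2) return(NA_real_)
    100 * sqrt(mean((a - mean(a))^2)) / mean(a)
  }, numeric(1))
  names(out) <- lv
  out
}

#' Empirical cumulative distributions of reflex amplitudes across pools
#'
#' Computes the ECDF of the significant-unit amplitudes of each study at
#' one activation level, plus pairwise signed dominance gaps: positive
#' values of `shift[i, j]` mean pool i tends to larger amplitudes than
#' pool j (its ECDF lies to the right).
#'
#' @param studies named list of [run_pool_study()] results (one per pool
#'   composition, simulated at the same level with shared stimulus seeds).
#' @param level activation level to compare.
#' @param method "psf" or "psth".
#' @return A list of class `ecdf_comparison`: `ecdf` (named list of ECDF
#'   functions), `amplitudes`, `shift` (matrix of mean-difference shifts),
#'   `max_gap` (matrix of maximal vertical ECDF gaps).
#' @export
amplitude_ecdf <- function(studies, level, method = c("psf", "psth")) {
  method <- match.arg(method)
  amp_col <- paste0(method, "_amp")
  sig_col <- paste0(method, "_sig")
  if (is.null(names(studies))) names(studies) <- seq_along(studies)
  amps <- lapply(studies, function(s) {
    a <- s[[amp_col]][s$level == level & s[[sig_col]]]
    a[is.finite(a)]
  })
  if (any(!lengths(amps)))
    stop("a pool has no significant units at this level")
  np <- length(amps)
  shift <- gap <- matrix(0, np, np, dimnames = list(names(amps), names(amps)))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i == j) next
    shift[i, j] <- mean(amps[[i]]) - mean(amps[[j]])
    grid <- sort(unique(c(amps[[i]], amps[[j]])))
    gap[i, j] <- max(abs(stats::ecdf(amps[[i]])(grid) -
                           stats::ecdf(amps[[j]])(grid)))
  }
  structure(list(ecdf = lapply(amps, stats::ecdf), amplitudes = amps,
                 shift = shift, max_gap = gap, level = level,
                 method = method),
            class = "ecdf_comparison")
}

#' @export
print.ecdf_comparison <- function(x, ...) {
  cat(sprintf("ECDF comparison (%s, level %d): %d pools\n",
              toupper(x$method), x$level, length(x$amplitudes)))
  cat("mean-amplitude shifts (row minus column):\n")
  print(round(x$shift, 4))
  invisible(x)
}

#' @export
plot.ecdf_comparison <- function(x, ...) {
  rng <- range(unlist(x$amplitudes))
  cols <- seq_along(x$amplitudes)
  plot(NA, xlim = rng, ylim = c(0, 1), xlab = sprintf(
    "%s amplitude (%s/stim)", toupper(x$method),
    if (x$method == "psf") "Hz" else "counts"),
    ylab = "cumulative probability", ...)
  for (i in cols) lines(x$ecdf[[i]], col = i, do.points = FALSE)
  legend("bottomright", legend = names(x$amplitudes), col = cols, lty = 1,
         bty = "n")
  invisible(x)
}

#' Track per-unit reflex amplitudes across activation levels
#'
#' Builds the unit-by-level amplitude matrix for one method and summary
#' flags: whether a unit's amplitude trajectory is monotone non-increasing
#' across the levels where it is significant, and whether it is U-shaped
#' (first decreases, then increases).
#'
#' @param study a [run_pool_study()] result.
#' @param method "psf" or "psth".
#' @param significant_only use only significant estimates (default TRUE).
#' @return A list of class `unit_tracking`: `amplitude` (matrix units x
#'   levels), `monotone_decrease`, `u_shape` (logical per unit).
#' @export
track_units <- function(study, method = c("psf", "psth"),
                        significant_only = TRUE) {
  method <- match.arg(method)
  amp_col <- paste0(method, "_amp")
  sig_col <- paste0(method, "_sig")
  lv <- sort(unique(study$level))
  un <- sort(unique(study$neuron))
  m <- matrix(NA_real_, length(un), length(lv),
              dimnames = list(un, lv))
  for (r in seq_len(nrow(study))) {
    if (significant_only && !study[[sig_col]][r]) next
    m[as.character(study$neuron[r]), as.character(study$level[r])] <-
      study[[amp_col]][r]
  }
  flag <- function(a) {
    a <- a[is.finite(a)]
    if (length(a) < 3) return(c(mono = NA, u = NA))
    d <- diff(a)
    mono <- all(d <= 1e-12)
    # U-shape: strictly falls somewhere before it strictly rises
    fell <- which(d < 0)
    rose <- which(d > 0)
    u <- length(fell) > 0 && length(rose) > 0 && min(fell) < max(rose) &&
      all(rose > max(fell))
    c(mono = mono, u = u)
  }
  fl <- t(apply(m, 1, flag))
  structure(list(amplitude = m,
                 monotone_decrease = as.logical(fl[, 1]),
                 u_shape = as.logical(fl[, 2]),
                 method = method),
            class = "unit_tracking")
}

#' @export
print.unit_tracking <- function(x, ...) {
  ok <- is.finite(x$monotone_decrease) | is.finite(x$u_shape)
  cat(sprintf("Unit tracking (%s): %d units x %d levels\n",
              toupper(x$method), nrow(x$amplitude), ncol(x$amplitude)))
  cat(sprintf("  monotone decreasing: %d, U-shaped: %d (of %d rateable)\n",
              sum(x$monotone_decrease, na.rm = TRUE),
              sum(x$u_shape, na.rm = TRUE), sum(ok)))
  invisible(x)
}

#' Pooled two-group regression
#'
#' Fits the amplitude regression separately within two externally defined
#' groups of units (group membership is an input, not inferred).
#'
#' @param x predictor (e.g. CoV of the ISI).
#' @param y response (e.g. reflex amplitude, standardized internally).
#' @param group factor or vector with exactly two levels.
#' @return Named list of [amplitude_regression()] results, one per group.
#' @export
grouped_regression <- function(x, y, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("'group' must have exactly two levels")
  out <- lapply(levels(g), function(l)
    amplitude_regression(x[g == l], y[g == l]))
  names(out) <- levels(g)
  out
}
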