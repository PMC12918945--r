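# Population statistics: z-score, regression, one-tailed correlation,
# amplitude dispersion, ECDF comparison, unit tracking.

test_that("zscore standardizes with the population SD", {
  expect_equal(zscore(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  z <- zscore(rnorm(50))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)     # idempotent
  expect_error(zscore(rep(2, 5)), "variance")
})

test_that("regression recovers exact linear relations", {
  x <- 1:20
  r <- suppressWarnings(amplitude_regression(x, 2 * x, standardize = FALSE))
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_equal(r$r2, 1, tolerance = 1e-10)
  expect_error(amplitude_regression(rep(1, 5), rnorm(5)), "degenerate")
  # standardization does not change R^2 or the p-value (affine invariance)
  set.seed(12)
  y <- 3 * x + rnorm(20, sd = 5)
  a <- amplitude_regression(x, y, standardize = FALSE)
  b <- amplitude_regression(x, y, standardize = TRUE)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("slope p-values are uniform under the null", {
  set.seed(77)
  p <- replicate(300, amplitude_regression(rnorm(12), rnorm(12))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("one-tailed Pearson correlation reports rho, p and rating", {
  x <- 1:10
  r <- pearson_one_tailed(x, 2 * x + 1, "positive")
  expect_equal(r$rho, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-6)
  expect_equal(r$rating, "strong")
  # ratings at the conventional band edges
  expect_equal(reflexpool:::.cor_rating(0.1), "poor")
  expect_equal(reflexpool:::.cor_rating(0.4), "fair")
  expect_equal(reflexpool:::.cor_rating(-0.6), "moderate")
  expect_equal(reflexpool:::.cor_rating(0.9), "strong")
  # one-tailed p in the wrong direction is large
  expect_gt(pearson_one_tailed(x, -x, "positive")$p, 0.99)
  expect_error(pearson_one_tailed(x, rep(1, 10), "positive"), "variance")
})

test_that("amplitude CoV uses the population SD among significant units", {
  st <- data.frame(level = c(1, 1, 1, 2, 2),
                   neuron = c(1, 2, 3, 1, 2),
                   psf_amp = c(1, 1, 2, 3, 3),
                   psf_sig = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  cov <- amplitude_cov(st, "psf")
  expect_equal(unname(cov["1"]), 35.35534, tolerance = 1e-4)
  expect_equal(unname(cov["2"]), 0)
  st$psf_sig[5] <- FALSE                            # < 2 significant units
  expect_true(is.na(amplitude_cov(st, "psf")["2"]))
})

test_that("ECDF comparison detects identical and shifted pools", {
  mk <- function(a) data.frame(level = 3, neuron = seq_along(a),
                               psf_amp = a, psf_sig = TRUE)
  a <- seq(0.5, 1.5, length.out = 30)
  cmp <- amplitude_ecdf(list(p1 = mk(a), p2 = mk(a)), level = 3, "psf")
  expect_equal(cmp$shift["p1", "p2"], 0)
  expect_equal(cmp$max_gap["p1", "p2"], 0)
  cmp2 <- amplitude_ecdf(list(lo = mk(a), hi = mk(a + 0.3)), level = 3, "psf")
  expect_lt(cmp2$shift["lo", "hi"], 0)
  expect_gt(cmp2$max_gap["lo", "hi"], 0.25)
  none <- mk(a)
  none$psf_sig <- FALSE
  expect_error(amplitude_ecdf(list(mk(a), none), 3, "psf"), "significant")
})

test_that("unit tracking flags flat, decreasing and U-shaped trajectories", {
  st <- expand.grid(neuron = 1:3, level = 1:5)
  st$psth_sig <- TRUE
  st$psth_amp <- NA_real_
  traj <- list(`1` = rep(0.3, 5),                       # flat
               `2` = c(0.5, 0.4, 0.3, 0.25, 0.25),      # decreasing
               `3` = c(0.5, 0.3, 0.2, 0.3, 0.5))        # U-shape
  for (r in seq_len(nrow(st)))
    st$psth_amp[r] <- traj[[as.character(st$neuron[r])]][st$level[r]]
  tk <- track_units(st, "psth")
  expect_equal(dim(tk$amplitude), c(3, 5))
  expect_true(tk$monotone_decrease[1])                  # flat is non-increasing
  expect_true(tk$monotone_decrease[2])
  expect_false(tk$monotone_decrease[3])
  expect_false(tk$u_shape[2])
  expect_true(tk$u_shape[3])
})

test_that("grouped regression fits each externally defined group", {
  set.seed(9)
  x <- runif(40, 10, 30)
  g <- rep(c("a", "b"), each = 20)
  y <- ifelse(g == "a", 2 * x, -x) + rnorm(40, sd = 2)
  out <- grouped_regression(x, y, g)
  expect_named(out, c("a", "b"))
  expect_gt(out$a$slope, 0)
  expect_lt(out$b$slope, 0)
  expect_error(grouped_regression(x, y, rep("a", 40)), "two levels")
})
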