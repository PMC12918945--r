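# PSTH / PSF construction, cusum algebra, error box, automated detector.

test_that("PSTH bins stimulus-locked spikes where they belong", {
  stim <- regular_stimuli(50)
  # one spike exactly 5 ms after every stimulus and nothing else
  tr <- spike_train(as.numeric(stim) + 5)
  ps <- peristimulus(tr, stim, "psth")
  k <- which(ps$edges == 5)                        # bin [5, 6)
  expect_equal(ps$values[k], 50)
  expect_equal(sum(ps$values), 50)
  # empty train: all-zero histogram
  ps0 <- peristimulus(spike_train(numeric(0), 1000), stim, "psth")
  expect_true(all(ps0$values == 0))
  expect_error(peristimulus(tr, numeric(0), "psth"), "empty")
  expect_error(peristimulus(tr, stim, "psth", bin_width = 7), "divide")
})

test_that("PSTH mass equals the number of peristimulus spikes", {
  set.seed(11)
  tr <- surrogate_train(13, 18, 61000, seed = 11)
  stim <- regular_stimuli(50, isi = 1100)
  ps <- peristimulus(tr, stim, "psth", window = c(200, 100))
  tt <- as.numeric(tr)
  n_direct <- sum(vapply(as.numeric(stim), function(on)
    sum(tt >= on - 200 & tt < on + 100), numeric(1)))
  expect_equal(sum(ps$values), n_direct)
})

test_that("PSF weights each discharge by its instantaneous rate", {
  stim <- regular_stimuli(30)
  tr <- periodic_train(10, 32000)
  ps <- peristimulus(tr, stim, "psf")
  # every contributing spike adds exactly 10 Hz
  psth <- peristimulus(tr, stim, "psth")
  first_spike_bins <- psth$values > 0
  expect_equal(ps$values[first_spike_bins] / psth$values[first_spike_bins],
               rep(10, sum(first_spike_bins)))
  # halved ISI after each stimulus doubles the post-stimulus PSF rate
  tt <- as.numeric(tr)
  for (on in as.numeric(stim)) {
    nxt <- which(tt > on)[1]
    tt[nxt] <- tt[nxt] - 50                        # ISI 100 -> 50 ms
  }
  ps2 <- peristimulus(spike_train(tt, 32000), stim, "psf")
  post <- ps2$edges[-1] > 0 & ps2$edges[-1] <= 60
  expect_equal(max(ps2$values[post]), 20 * 30)     # 20 Hz for all 30 trials
  # empty train gives an all-zero PSF
  expect_true(all(peristimulus(spike_train(numeric(0), 1000),
                               stim, "psf")$values == 0))
})

test_that("cusum is zero for flat data and at the last pre-stimulus bin", {
  stim <- regular_stimuli(10)
  tr <- periodic_train(10, 12000)
  for (m in c("psth", "psf")) {
    ct <- ps_cusum(peristimulus(tr, stim, m))
    expect_equal(ct$cusum[max(ct$pre_idx)], 0, tolerance = 1e-9)
  }
  # a single elevated bin produces a step of its height above baseline
  ps <- peristimulus(spike_train(as.numeric(stim) + 5), stim, "psth")
  ct <- ps_cusum(ps)
  expect_equal(ct$baseline, 0)                     # empty pre-stimulus region
  expect_equal(max(ct$cusum), 10)                  # step of the bin height
  expect_equal(ct$cusum[length(ct$cusum)], 10)     # no further drift
})

test_that("error box requires strict exceedance", {
  stim <- regular_stimuli(40)
  tr <- spike_train(as.numeric(stim) + 5)
  ct <- ps_cusum(peristimulus(tr, stim, "psth"))
  expect_equal(error_box(ct), 0)                   # empty pre-stimulus region
  fit <- reflex_fit(tr, stim, method = "psth")
  expect_true(fit$estimate$significant)
  # flat cusum: no response, no crash
  flat <- reflex_fit(periodic_train(10, 42000), stim, method = "psth")
  expect_false(flat$estimate$significant)
  expect_equal(flat$estimate$amplitude_norm, 0)
  expect_true(is.na(flat$estimate$onset))
})

test_that("detector recovers a deterministic injected response exactly", {
  stim <- regular_stimuli(100)
  tr <- periodic_train(9.7, 102000, phase = 13)
  inj <- inject_reflex(tr, stim, prob = 1, latency = 5, seed = 2)
  fit <- reflex_fit(inj$train, stim, method = "psth")
  expect_true(fit$estimate$significant)
  expect_equal(fit$estimate$onset, 5, tolerance = 1)
  expect_equal(fit$estimate$amplitude_norm, 1, tolerance = 0.05)
  # coef() exposes the estimate
  cf <- coef(fit)
  expect_equal(unname(cf["amplitude_norm"]), fit$estimate$amplitude_norm)
  expect_equal(unname(cf["duration"]),
               fit$estimate$end - fit$estimate$onset)
})

test_that("PSF and PSTH agree on onset for a pure added discharge", {
  stim <- regular_stimuli(120)
  tr <- surrogate_train(11, 14, 122000, seed = 21)
  inj <- inject_reflex(tr, stim, prob = 0.8, latency = 6, seed = 22)
  f1 <- reflex_fit(inj$train, stim, method = "psth")
  f2 <- reflex_fit(inj$train, stim, method = "psf")
  expect_true(f1$estimate$significant && f2$estimate$significant)
  expect_lte(abs(f1$estimate$onset - f2$estimate$onset), 1)
})

test_that("experimental mode uses the shorter window without onset bound", {
  stim <- regular_stimuli(80, isi = 700)
  tr <- surrogate_train(10, 12, 58000, seed = 5)
  inj <- inject_reflex(tr, stim, prob = 1, latency = 40, seed = 6)
  # 40 ms latency: rejected in simulated mode, accepted in experimental
  fs <- reflex_fit(inj$train, stim, method = "psth", mode = "simulated")
  fe <- reflex_fit(inj$train, stim, method = "psth", mode = "experimental")
  expect_true(is.na(fs$estimate$onset))
  expect_equal(fe$estimate$onset, 40, tolerance = 1)
  expect_equal(fe$ps$window, c(pre = 200, post = 100))
  expect_equal(fs$ps$window, c(pre = 300, post = 150))
})

test_that("reflex_fit methods print, summarise and expose residuals", {
  stim <- regular_stimuli(40)
  tr <- periodic_train(10, 42000)
  inj <- inject_reflex(tr, stim, prob = 1, latency = 5, seed = 3)
  fit <- reflex_fit(inj$train, stim, method = "psth")
  expect_output(print(fit), "Reflex fit")
  expect_output(print(summary(fit)), "error box")
  r <- residuals(fit)
  expect_length(r, length(fit$ps$values))
  expect_equal(mean(r[fit$cusum$pre_idx]), 0, tolerance = 1e-12)
})
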