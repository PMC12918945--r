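# Synaptic input components: EPSC waveform, stimulus train, common and
# independent noise, exact assembly.

test_that("EPSC waveform follows the alpha-like form with peak at tau", {
  expect_equal(epsc_waveform(1), 6)                       # peak = gain at tau
  expect_equal(epsc_waveform(0), 0)
  expect_equal(epsc_waveform(2), 12 * exp(-1))            # 6 * 2 * e^(1-2)
  expect_equal(epsc_waveform(c(0.5, 1, 3), gain = 2, tau = 1),
               2 * c(0.5, 1, 3) * exp(1 - c(0.5, 1, 3)))
  expect_equal(epsc_waveform(41), 0)                      # beyond support
  expect_error(epsc_waveform(-1), "non-negative")
})

test_that("stimulus trains have the configured interval statistics", {
  st <- stimulus_train(200, seed = 7)
  expect_length(as.numeric(st), 200)
  isi <- diff(as.numeric(st))
  expect_true(abs(mean(isi) - 1000) < 30)
  expect_true(abs(sd(isi) - 100) < 30)
  expect_true(all(isi >= 200))                            # truncation bound
  # determinism and degenerate cases
  expect_identical(as.numeric(stimulus_train(50, seed = 3)),
                   as.numeric(stimulus_train(50, seed = 3)))
  expect_length(as.numeric(stimulus_train(1, seed = 1)), 1)
  st0 <- stimulus_train(10, sd_isi = 0, seed = 1)
  expect_equal(unique(diff(as.numeric(st0))), 1000)
})

test_that("common input has the configured mean, SD and band", {
  cfg <- input_config(mean_drive = 10, duration = 100000, seed = 5)
  tr <- common_input(cfg)
  expect_true(abs(mean(tr) - 10) < 0.1)
  expect_true(abs(sd(tr) - 2) / 2 < 0.05)                 # 20 % of mean
  # noise-free configuration is exactly constant
  cfg0 <- input_config(mean_drive = 10, duration = 1000, common_sd_frac = 0)
  expect_true(all(as.numeric(common_input(cfg0)) == 10))
  # determinism
  expect_identical(as.numeric(common_input(cfg)), as.numeric(common_input(cfg)))
  # spectral mass concentrated in the 15-35 Hz band (on the coarse grid)
  x <- as.numeric(tr)[seq(1, length(tr), by = 20)] - 10   # back to 1 kHz
  spec <- Mod(fft(x))^2
  freq <- (seq_along(spec) - 1) / length(spec) * 1000
  half <- freq <= 500
  inband <- half & freq >= 13 & freq <= 38
  expect_gt(sum(spec[inband]) / sum(spec[half]), 0.8)
})

test_that("independent noise has the configured share and is uncorrelated", {
  cfg <- input_config(mean_drive = 10, duration = 100000, seed = 9)
  a <- independent_noise(cfg, 101)
  b <- independent_noise(cfg, 202)
  expect_true(abs(mean(a)) < 0.05)
  # variance share: var_indep / (var_common_noise + var_indep) ~ 0.20
  vc <- (0.2 * 10)^2
  share <- var(as.numeric(a)) / (vc + var(as.numeric(a)))
  expect_true(abs(share - 0.2) < 0.03)
  expect_lt(abs(cor(as.numeric(a), as.numeric(b))), 0.05)
  cfg0 <- input_config(mean_drive = 10, duration = 1000, indep_share = 0)
  expect_true(all(as.numeric(independent_noise(cfg0, 1)) == 0))
})

test_that("input assembly is exactly additive", {
  n <- 2000
  dt <- 0.05
  stim <- regular_stimuli(3, isi = 30, start = 10)
  sc <- stimulus_current(stim, n, dt)
  cm <- current_trace(rep(2, n), dt, "common")
  ind <- current_trace(sin(seq_len(n) / 50), dt, "independent")
  tot <- assemble_input(cm, ind, sc)
  expect_equal(as.numeric(tot), 2 + sin(seq_len(n) / 50) + as.numeric(sc))
  # single stimulus with zero noise reproduces the shifted waveform
  one <- stimulus_current(regular_stimuli(1, start = 5), n, dt)
  tvals <- (seq_len(n) - 1) * dt
  after <- tvals >= 5 & tvals <= 45
  expect_equal(as.numeric(one)[after],
               epsc_waveform(tvals[after] - 5), tolerance = 1e-10)
  expect_true(all(as.numeric(one)[tvals < 5] == 0))
  # component integrals sum to the total integral
  expect_equal(sum(tot), sum(cm) + sum(ind) + sum(sc))
  expect_error(assemble_input(cm, current_trace(1:5, dt)), "grids")
})

test_that("input configuration rejects invalid noise settings", {
  expect_error(input_config(10, 1000, common_band = c(35, 15)), "band")
  expect_error(input_config(10, 1000, common_band = c(15, 600)), "band")
  expect_error(input_config(10, 1000, indep_share = 1.2), "fraction")
  expect_error(input_config(-1, 1000), "mean_drive")
})
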