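make_nn <- function(ms) {
  s <- rr_series(ms / 1000, rep("N", length(ms)))
  estimate_nn_series(s)
}

test_that("time-domain indices match hand-computed values", {
  td <- time_domain_indices(make_nn(rep(800, 10)))
  expect_equal(td$meanNN, 800)
  expect_equal(td$SDNN, 0)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$pNN50, 0)

  # successive differences 60, -60, 60: RMSSD 60 ms, all |d| > 50
  td <- time_domain_indices(make_nn(c(800, 860, 800, 860)))
  expect_equal(td$RMSSD, 60)
  expect_equal(td$pNN50, 100)

  # |d| = 45 is not > 50: strict threshold
  expect_equal(time_domain_indices(make_nn(c(800, 845, 800)))$pNN50, 0)
  expect_error(time_domain_indices(0.8), "at least 2")
})

test_that("time-domain indices agree with a two-pass oracle to 1e-9", {
  set.seed(31)
  for (i in 1:25) {
    x <- runif(sample(5:400, 1), 400, 1200)
    got <- time_domain_indices(make_nn(x))
    ref <- oracle_time_domain(x)
    expect_equal(got$meanNN, ref$meanNN, tolerance = 1e-9)
    expect_equal(got$SDNN, ref$SDNN, tolerance = 1e-9)
    expect_equal(got$RMSSD, ref$RMSSD, tolerance = 1e-9)
    expect_equal(got$pNN50, ref$pNN50, tolerance = 1e-9)
  }
})

test_that("last-minute indices use the maximal suffix within the window", {
  lm1 <- last_minute_indices(make_nn(rep(1000, 600)), 60)
  expect_equal(lm1$meanNN_lm, 1000)
  expect_equal(lm1$SDNN_lm, 0)

  # final 60 s holds exactly one hundred 600 ms intervals; the earlier
  # 1000 ms intervals must not leak into the window
  x <- c(rep(1000, 100), rep(600, 100))
  lm2 <- last_minute_indices(make_nn(x), 60)
  expect_equal(lm2$meanNN_lm, 600)
  expect_equal(lm2$SDNN_lm, 0)

  # window = full duration reproduces the global time-domain indices
  x3 <- c(900, 700, 850, 820, 780)
  lm3 <- last_minute_indices(make_nn(x3), sum(x3) / 1000)
  td3 <- time_domain_indices(make_nn(x3))
  expect_equal(lm3$meanNN_lm, td3$meanNN)
  expect_equal(lm3$SDNN_lm, td3$SDNN)

  expect_error(last_minute_indices(make_nn(rep(800, 10)), 60), "shorter")
})

test_that("resampling yields an exact 1/3 s grid that tracks the signal", {
  r <- resample_nn(make_nn(rep(800, 500)))
  expect_equal(unique(round(diff(r$time), 12)), 1 / 3)
  expect_equal(max(abs(r$nn_ms - 800)), 0, tolerance = 1e-9)
  expect_lte(max(r$time), 0.8 * 500)

  # linear ramp 800 -> 1000 ms: cubic interpolation within 1 ms of the line
  n <- 300
  ramp <- seq(800, 1000, length.out = n)
  nn <- make_nn(ramp)
  t_beat <- cumsum(ramp / 1000)
  line <- approxfun(t_beat, ramp)
  r2 <- resample_nn(nn)
  expect_lt(max(abs(r2$nn_ms - line(r2$time))), 1)

  expect_error(resample_nn(make_nn(c(800, 810, 790))), "at least 4")
})

test_that("Welch band powers concentrate a pure sinusoid in its band", {
  cfg <- spectral_config()
  t <- seq(0, 300 - 1 / 3, by = 1 / 3)
  for (f0 in c(0.10, 0.30)) {
    sig <- 800 + 50 * sin(2 * pi * f0 * t)
    bp <- welch_band_powers(sig, cfg)
    share <- if (f0 < 0.15) bp$LF / (bp$LF + bp$HF) else bp$HF / (bp$LF + bp$HF)
    expect_gt(share, 0.95)
    # one-sided density normalization: band integral ~ amplitude^2 / 2
    expect_equal(unlist(bp[if (f0 < 0.15) "LF" else "HF"]) / (50^2 / 2), 1,
                 tolerance = 0.05, ignore_attr = TRUE)
  }
  flat <- welch_band_powers(rep(800, 900), cfg)
  expect_lt(flat$LF + flat$HF, 1e-10 * 800)
  expect_error(welch_band_powers(rep(800, 100), cfg), "shorter than one")
})

test_that("segment-averaged indices equal the mean of per-segment values", {
  s <- generate_recording(synth_params(mean_nn = 700, pvc_rate = 0),
                          seed = 13)
  nn <- estimate_nn_series(s)
  cfg <- spectral_config()
  got <- spectral_indices(nn, cfg)

  sig <- resample_nn(nn, cfg)$nn_ms
  seg_len <- 900
  n_seg <- length(sig) %/% seg_len
  offset <- length(sig) - n_seg * seg_len
  per <- lapply(seq_len(n_seg), function(i) {
    welch_band_powers(sig[(offset + (i - 1) * seg_len + 1):
                            (offset + i * seg_len)], cfg)
  })
  lf <- vapply(per, function(x) x$LF, numeric(1))
  hf <- vapply(per, function(x) x$HF, numeric(1))
  expect_equal(got$LF, mean(lf))
  expect_equal(got$HF, mean(hf))
  expect_equal(got$LF_HF, mean(lf / hf))
  expect_equal(got$LFnu + got$HFnu, 100)
})

test_that("LF/HF follows the squared amplitude ratio of planted sinusoids", {
  s <- generate_recording(synth_params(mean_nn = 800, sd_noise = 0,
                                       lf_amp = 40, hf_amp = 20,
                                       pvc_rate = 0), seed = 17)
  sp <- spectral_indices(estimate_nn_series(s))
  expect_equal(sp$LF_HF, 4, tolerance = 0.15)
})

test_that("index scaling behaves as the definitions require", {
  set.seed(23)
  x <- runif(300, 600, 1000)
  td <- time_domain_indices(make_nn(x))
  td_c <- time_domain_indices(make_nn(2.5 * x))
  expect_equal(td_c$meanNN, 2.5 * td$meanNN)
  expect_equal(td_c$SDNN, 2.5 * td$SDNN)
  expect_equal(td_c$RMSSD, 2.5 * td$RMSSD)

  # pNN50 invariant to a constant shift of all intervals
  expect_equal(time_domain_indices(make_nn(x + 200))$pNN50, td$pNN50)

  # amplitude scaling of the tachogram signal leaves normalized powers
  # untouched (both band powers scale by c^2)
  cfg <- spectral_config()
  t <- seq(0, 300 - 1 / 3, by = 1 / 3)
  sig <- 800 + 30 * sin(2 * pi * 0.1 * t) + 20 * sin(2 * pi * 0.3 * t)
  b1 <- welch_band_powers(sig, cfg)
  b2 <- welch_band_powers(sig * 3, cfg)
  expect_equal(b2$LF / (b2$LF + b2$HF), b1$LF / (b1$LF + b1$HF))
  expect_equal(b2$LF, 9 * b1$LF)
})

test_that("raising the 0.1 Hz amplitude never lowers LF/HF", {
  ratios <- vapply(c(5, 15, 30, 45), function(a) {
    s <- generate_recording(synth_params(mean_nn = 750, sd_noise = 2,
                                         lf_amp = a, hf_amp = 15,
                                         pvc_rate = 0), seed = 29)
    spectral_indices(estimate_nn_series(s))$LF_HF
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
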