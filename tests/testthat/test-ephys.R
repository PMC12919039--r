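# MUA envelope processing, SNR computation and weekly aggregation.

make_trials <- function(n_trials, n_time = 1500, rate = 1000, noise = 1,
                        bump = NULL, seed = 1) {
  # time axis -0.25 .. 1.25 s at 1 kHz
  set.seed(seed)
  tt <- seq(-0.25, by = 1 / rate, length.out = n_time)
  m <- matrix(rnorm(n_trials * n_time, 0, noise), n_trials, n_time)
  if (!is.null(bump)) {
    shape <- bump$a * exp(-(tt - bump$t0)^2 / (2 * bump$sd^2))
    m <- sweep(m, 2, shape, `+`)
  }
  structure(list(trials = m, time_s = tt, rate_hz = rate, n_dropped = 0L),
            class = "trial_matrix")
}

test_that("common average reference cancels shared components", {
  set.seed(20)
  sig <- matrix(rnorm(4 * 1000), 4, 1000)
  sig0 <- sweep(sig, 2, colMeans(sig))      # zero-mean reference

  # identical signal on all channels vanishes
  shared <- matrix(rep(sin(1:1000 / 10), each = 4), 4, 1000)
  expect_true(all(abs(common_average_reference(shared)) < 1e-12))

  # column sums of any referenced output are zero
  out <- common_average_reference(sig)
  expect_true(all(abs(colSums(out)) < 1e-9))

  # shared sinusoid is removed exactly
  art <- sweep(sig, 2, 5 * sin(2 * pi * 8 * (1:1000) / 1000), `+`)
  expect_equal(common_average_reference(art), sig0, tolerance = 1e-9)

  expect_warning(common_average_reference(sig[1, , drop = FALSE]), "single")
})

test_that("MUA envelope rejects out-of-band input and tracks in-band amplitude", {
  fs <- 24000
  tt <- (0:(fs / 2)) / fs
  # 100 Hz is far below the 750 Hz corner: attenuation >= 40 dB
  lowf <- sin(2 * pi * 100 * tt)
  env_low <- mua_envelope(lowf, fs)
  expect_lt(mean(env_low[1000:11000]), 2 / pi * 0.01)

  # 2 kHz sine of amplitude A: rectified mean 2A/pi
  A <- 3
  inband <- A * sin(2 * pi * 2000 * tt)
  env_in <- mua_envelope(inband, fs)
  mid <- env_in[2000:10000]
  expect_equal(mean(mid), 2 * A / pi, tolerance = 0.05)
  expect_lt(sd(mid), 0.05 * A)

  expect_true(all(mua_envelope(numeric(5000), fs) == 0))
  expect_error(mua_envelope(numeric(100), 8000), "sampling rate")
})

test_that("epoching slices trials and averages correctly", {
  env <- rep(4, 10000)   # constant envelope at 1 kHz
  tm <- epoch_and_average(env, 1000, onsets_s = c(1, 3, 5))
  expect_equal(dim(tm$trials), c(3, 1500))
  expect_true(all(tm$trials == 4))
  expect_equal(range(tm$time_s), c(-0.25, 1.25 - 1e-3))

  # truncated trials are dropped with a message
  expect_message(
    tm2 <- epoch_and_average(env, 1000, onsets_s = c(0.1, 2, 9.9)),
    "dropped 2")
  expect_equal(nrow(tm2$trials), 1)
  expect_equal(tm2$n_dropped, 2L)

  # single trial: mean equals that trial
  env3 <- seq_len(5000) / 1000
  tm3 <- epoch_and_average(env3, 1000, onsets_s = 2)
  expect_equal(as.numeric(colMeans(tm3$trials)), as.numeric(tm3$trials[1, ]))
})

test_that("compute_snr estimates A/sigma and picks the largest window", {
  # deterministic bump of height A at 100 ms on i.i.d. noise
  A <- 1.5; noise <- 1; n_trials <- 100
  snrs <- vapply(1:20, function(s) {
    tm <- make_trials(n_trials, noise = noise,
                      bump = list(a = A, t0 = 0.1, sd = 0.025), seed = s)
    compute_snr(tm)$snr
  }, numeric(1))
  sigma <- noise / sqrt(250)   # SD of per-trial baseline means
  expect_lt(abs(median(snrs) - A / sigma) / (A / sigma), 0.10)

  # a larger bump in the reversal window wins the window selection
  tm <- make_trials(60, bump = list(a = 2, t0 = 0.1, sd = 0.02), seed = 99)
  shape2 <- 5 * exp(-(tm$time_s - 0.6)^2 / (2 * 0.02^2))
  tm$trials <- sweep(tm$trials, 2, shape2, `+`)
  s <- compute_snr(tm)
  expect_equal(s$window, "reversal")

  # suppressed (negative) responses count through the absolute value
  tmneg <- make_trials(60, bump = list(a = -3, t0 = 0.62, sd = 0.02),
                       seed = 7)
  expect_equal(compute_snr(tmneg)$window, "reversal")

  # scale invariance of the ratio
  tm2 <- make_trials(50, bump = list(a = 2, t0 = 0.1, sd = 0.02), seed = 3)
  tm3 <- tm2; tm3$trials <- tm3$trials * 17
  expect_equal(compute_snr(tm2)$snr, compute_snr(tm3)$snr, tolerance = 1e-9)

  # zero-noise trials are flagged invalid
  tmz <- make_trials(5, noise = 0, bump = list(a = 1, t0 = 0.1, sd = 0.02))
  tmz$trials <- tmz$trials + 0 * tmz$trials
  expect_warning(sz <- compute_snr(tmz), "zero baseline noise")
  expect_false(sz$valid)
  expect_true(is.na(sz$snr))
})

test_that("the null SNR level sits far below an evoked response", {
  # no evoked component: the max-over-windows statistic has a positive
  # null level (it is a maximum of noise), estimated here by simulation
  snr0 <- vapply(1:40, function(s) {
    compute_snr(make_trials(40, noise = 1, seed = s + 500))$snr
  }, numeric(1))
  expect_lt(median(snr0), 3)

  snr_ev <- vapply(1:10, function(s) {
    compute_snr(make_trials(40, noise = 1,
                            bump = list(a = 1.5, t0 = 0.1, sd = 0.025),
                            seed = s + 700))$snr
  }, numeric(1))
  expect_gt(median(snr_ev), 5 * median(snr0))
})

test_that("CAR improves SNR in the presence of a common-mode artifact", {
  ep <- ephys_model_params(n_electrodes = 4, n_trials = 12,
                           evoked_amplitude = 4, noise_sd = 0.5,
                           artifact_amp = 2, burst_rate_hz = 2,
                           burst_amp = 6, seed = 8)
  rec <- generate_mua_recording(ep, week = 0)
  with_car <- process_recording(rec, car = TRUE)
  without <- process_recording(rec, car = FALSE)
  expect_gt(median(with_car$snr), median(without$snr))
})

test_that("weekly aggregation averages sessions and derives fractions", {
  rec <- data.frame(
    electrode = c(1, 1, 2, 1, 2),
    week = c(1, 1, 1, 2, 2),
    material = "PI",
    snr = c(2, 4, 0.5, 0.8, 3))
  agg <- weekly_aggregate(rec)
  w11 <- agg$weekly[agg$weekly$electrode == 1 & agg$weekly$week == 1, ]
  expect_equal(w11$snr, 3)                    # sessions averaged
  expect_equal(agg$fraction$pct_useful[agg$fraction$week == 1], 50)
  expect_equal(agg$fraction$pct_useful[agg$fraction$week == 2], 50)

  # snr exactly 1 or below is not "useful" (strict cutoff)
  rec2 <- data.frame(electrode = 1:3, week = 1, material = "Si",
                     snr = c(0.5, 1, 1.0001))
  agg2 <- weekly_aggregate(rec2)
  expect_equal(agg2$fraction$pct_useful, 100 / 3)
})
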