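#' Parameters of the synthetic evoked-recording model
#'
#' Describes a passive-viewing session: a full-screen checkerboard shown for
#' 500 ms, contrast-reversed for another 500 ms, with a 1 s inter-trial
#' interval, sampled at 24 kHz. Each stimulus evokes multi-unit-band
#' transients in up to three response windows (stimulus onset, pattern
#' reversal, stimulus offset), whose amplitude decays multiplicatively per
#' week of implantation. A shared-mode artifact (low-frequency sinusoid plus
#' broadband bursts common to all electrodes) emulates running and muscle
#' noise so that common-average referencing is observably beneficial.
#'
#' @param n_electrodes number of electrodes.
#' @param sampling_rate_hz sampling rate; must exceed twice the 5 kHz upper
#'   edge of the multi-unit band.
#' @param n_trials number of stimulus presentations.
#' @param evoked_amplitude standard-deviation multiplier of the evoked
#'   multi-unit-band transient at week 0.
#' @param evoked_latency_ms response latency after each window start.
#' @param evoked_windows subset of `c("onset", "reversal", "offset")`,
#'   i.e. transients at 0, 500 and 1000 ms after stimulus onset.
#' @param weekly_decay per-week multiplicative amplitude factor in (0, 1\].
#' @param noise_sd baseline broadband noise SD (arbitrary voltage units).
#' @param artifact_amp,artifact_freq_hz amplitude and frequency of the
#'   common-mode sinusoid.
#' @param burst_rate_hz,burst_amp rate and amplitude of common-mode
#'   broadband bursts (50 ms each).
#' @param seed integer RNG seed.
#' @return An object of class `ephys_model_params`.
#' @export
ephys_model_params <- function(n_electrodes = 8,
                               sampling_rate_hz = 24000,
                               n_trials = 100,
                               evoked_amplitude = 3,
                               evoked_latency_ms = 60,
                               evoked_windows = c("onset", "reversal", "offset"),
                               weekly_decay = 0.9,
                               noise_sd = 1,
                               artifact_amp = 2,
                               artifact_freq_hz = 8,
                               burst_rate_hz = 0.5,
                               burst_amp = 4,
                               seed = 1L) {
  stopifnot_scalar(n_electrodes, "n_electrodes", 1)
  stopifnot_scalar(sampling_rate_hz, "sampling_rate_hz", 10001)
  stopifnot_scalar(n_trials, "n_trials", 1)
  stopifnot_scalar(weekly_decay, "weekly_decay", 1e-12, 1)
  stopifnot_scalar(evoked_amplitude, "evoked_amplitude", 0)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  evoked_windows <- match.arg(evoked_windows,
                              c("onset", "reversal", "offset"),
                              several.ok = TRUE)
  p <- list(
    n_electrodes = as.integer(n_electrodes),
    sampling_rate_hz = sampling_rate_hz,
    n_trials = as.integer(n_trials),
    evoked_amplitude = evoked_amplitude,
    evoked_latency_ms = evoked_latency_ms,
    evoked_windows = evoked_windows,
    weekly_decay = weekly_decay,
    noise_sd = noise_sd,
    artifact_amp = artifact_amp,
    artifact_freq_hz = artifact_freq_hz,
    burst_rate_hz = burst_rate_hz,
    burst_amp = burst_amp,
    seed = as.integer(seed)
  )
  class(p) <- "ephys_model_params"
  p
}

#' Generate a synthetic multi-electrode recording of one session
#'
#' Per-electrode broadband Gaussian noise plus, at every stimulus event, a
#' variance transient (Gaussian temporal envelope, sigma 30 ms) in each
#' configured response window with amplitude
#' `evoked_amplitude * weekly_decay^week`, at the configured latency. A
#' common-mode artifact (sinusoid plus broadband bursts) is added
#' identically to all electrodes.
#'
#' Trials are 2 s long (1 s stimulus, 1 s inter-trial interval) after a 1 s
#' lead-in.
#'
#' @param params an [ephys_model_params()] object.
#' @param week non-negative integer week post implantation.
#' @return A `raw_recording`: list with `samples` (electrodes x samples
#'   matrix), `rate_hz`, `onsets_s`, `week`.
#' @export
generate_mua_recording <- function(params, week = 0) {
  stopifnot(inherits(params, "ephys_model_params"))
  stopifnot_scalar(week, "week", 0)
  fs <- params$sampling_rate_hz
  pre <- 1; trial_len <- 2; post <- 0.5
  onsets <- pre + (seq_len(params$n_trials) - 1) * trial_len
  n <- round((pre + params$n_trials * trial_len + post) * fs)
  t_axis <- (seq_len(n) - 1) / fs

  win_start <- c(onset = 0, reversal = 0.5, offset = 1.0)
  centers <- as.vector(outer(
    win_start[params$evoked_windows] + params$evoked_latency_ms / 1000,
    onsets, `+`
  ))
  amp <- params$evoked_amplitude * params$weekly_decay^week
  env_sd <- 0.03

  with_seed(params$seed + 131L * as.integer(week), {
    # amplitude-envelope vector shared across electrodes (deterministic
    # given the trial grid); evoked noise itself is per electrode
    a <- numeric(n)
    half <- round(4 * env_sd * fs)
    for (ctr in centers) {
      i0 <- max(1L, round(ctr * fs) - half)
      i1 <- min(n, round(ctr * fs) + half)
      idx <- i0:i1
      a[idx] <- a[idx] + exp(-(t_axis[idx] - ctr)^2 / (2 * env_sd^2))
    }
    evoked_idx <- which(a > 1e-3)

    common <- params$artifact_amp *
      sin(2 * pi * params$artifact_freq_hz * t_axis)
    n_burst <- rpois(1, params$burst_rate_hz * n / fs)
    if (n_burst > 0) {
      starts <- sort(floor(runif(n_burst) * (n - round(0.05 * fs))))
      blen <- round(0.05 * fs)
      for (s in starts) {
        idx <- (s + 1):(s + blen)
        common[idx] <- common[idx] + rnorm(blen, 0, params$burst_amp)
      }
    }

    samples <- matrix(0, params$n_electrodes, n)
    for (e in seq_len(params$n_electrodes)) {
      x <- rnorm(n, 0, params$noise_sd)
      if (length(evoked_idx) && amp > 0) {
        x[evoked_idx] <- x[evoked_idx] +
          amp * a[evoked_idx] * rnorm(length(evoked_idx))
      }
      samples[e, ] <- x + common
    }
    structure(
      list(samples = samples, rate_hz = fs, onsets_s = onsets,
           week = as.integer(week)),
      class = "raw_recording"
    )
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d electrode(s), %.1f s at %g Hz, %d trial(s), week %d\n",
    nrow(x$samples), ncol(x$samples) / x$rate_hz, x$rate_hz,
    length(x$onsets_s), x$week))
  invisible(x)
}
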