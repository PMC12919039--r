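# Visually evoked multi-unit activity (MUA) processing: common-average
# referencing, envelope extraction, epoching and SNR.

#' Common average reference
#'
#' Subtracts the per-sample mean across electrodes from every channel,
#' cancelling shared-mode artifacts (running, muscle noise). The channel
#' mean of the output is identically zero.
#'
#' @param rec a `raw_recording` (see [generate_mua_recording()]) or a plain
#'   electrodes x samples matrix.
#' @return Object of the same kind with re-referenced samples. A
#'   single-electrode recording is returned unchanged with a warning.
#' @export
common_average_reference <- function(rec) {
  m <- if (inherits(rec, "raw_recording")) rec$samples else rec
  if (nrow(m) < 2L) {
    warning("single electrode: common average reference is the identity")
    return(rec)
  }
  m <- sweep(m, 2, colMeans(m))
  if (inherits(rec, "raw_recording")) {
    rec$samples <- m
    rec
  } else {
    m
  }
}

# Cached zero-phase Butterworth designs.
.filter_cache <- new.env(parent = emptyenv())

butter_cached <- function(order, w, type) {
  key <- paste(order, paste(signif(w, 10), collapse = "-"), type)
  if (is.null(.filter_cache[[key]])) {
    .filter_cache[[key]] <- signal::butter(order, w, type = type)
  }
  .filter_cache[[key]]
}

#' MUA envelope of one channel
#'
#' Zero-phase band-pass (750-5000 Hz, 3rd-order Butterworth applied
#' forward-backward), full-wave rectification, then a zero-phase 200 Hz
#' low-pass. Output is non-negative up to filter ringing.
#'
#' @param x numeric vector, one channel of raw voltage.
#' @param rate_hz sampling rate; must be at least twice the band's upper
#'   edge.
#' @param band MUA band in Hz.
#' @param lowpass_hz smoothing low-pass corner in Hz.
#' @param order Butterworth order.
#' @return Envelope vector, same length as `x`.
#' @export
mua_envelope <- function(x, rate_hz, band = c(750, 5000), lowpass_hz = 200,
                         order = 3) {
  if (rate_hz < 2 * band[2]) {
    stop("sampling rate below twice the band's upper edge", call. = FALSE)
  }
  nyq <- rate_hz / 2
  bp <- butter_cached(order, band / nyq, "pass")
  lp <- butter_cached(order, lowpass_hz / nyq, "low")
  y <- abs(signal::filtfilt(bp, x))
  as.numeric(signal::filtfilt(lp, y))
}

#' Decimate an envelope to a lower rate
#'
#' After the 200 Hz low-pass the envelope carries no content near the new
#' Nyquist frequency, so plain subsampling is used.
#'
#' @param env envelope vector.
#' @param rate_hz current sampling rate.
#' @param target_hz output rate; must divide `rate_hz`.
#' @return List with `env` and `rate_hz`.
#' @export
decimate_envelope <- function(env, rate_hz, target_hz = 1000) {
  step <- rate_hz / target_hz
  if (abs(step - round(step)) > 1e-9) {
    stop("target rate must divide the sampling rate", call. = FALSE)
  }
  list(env = env[seq(1, length(env), by = round(step))], rate_hz = target_hz)
}

#' Epoch an envelope around stimulus onsets
#'
#' Cuts per-trial windows (default -0.25 s to +1.25 s relative to onset)
#' and stacks them into a trials x time matrix. Trials whose window falls
#' outside the recording are dropped and counted.
#'
#' @param env envelope vector.
#' @param rate_hz envelope sampling rate.
#' @param onsets_s stimulus onset times in seconds.
#' @param window two-element window in seconds relative to onset.
#' @return A `trial_matrix`: list with `trials` (matrix), `time_s` (axis
#'   relative to onset), `rate_hz`, `n_dropped`.
#' @export
epoch_and_average <- function(env, rate_hz, onsets_s,
                              window = c(-0.25, 1.25)) {
  i0 <- round(window[1] * rate_hz)
  i1 <- round(window[2] * rate_hz) - 1L
  rel <- i0:i1
  n <- length(env)
  keep <- vapply(onsets_s, function(o) {
    s <- round(o * rate_hz) + 1L
    s + i0 >= 1L && s + i1 <= n
  }, logical(1))
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropped %d truncated trial(s)", n_dropped))
  }
  ons <- onsets_s[keep]
  if (length(ons) == 0L) stop("no complete trials", call. = FALSE)
  trials <- t(vapply(ons, function(o) {
    s <- round(o * rate_hz) + 1L
    env[s + rel]
  }, numeric(length(rel))))
  structure(
    list(trials = trials, time_s = rel / rate_hz, rate_hz = rate_hz,
         n_dropped = n_dropped),
    class = "trial_matrix"
  )
}

gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- ceiling(4 * sd_samples)
  k <- stats::dnorm(-half:half, sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))   # edge replication
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Signal-to-noise ratio of the evoked MUA response
#'
#' The trial-mean envelope is smoothed (Gaussian kernel, default sigma
#' 5 ms). Baseline is the mean of the trial-mean trace over the 250 ms
#' before onset; noise is the standard deviation across trials of the
#' per-trial baseline means. The response is the maximum absolute
#' deviation of the smoothed trial-mean trace from baseline within three
#' candidate windows -- 0-250 ms (stimulus onset), 500-750 ms (pattern
#' reversal), 1-1.25 s (stimulus offset) -- and the window with the
#' largest magnitude is reported. SNR = response / noise. The absolute
#' value admits suppressed (below-baseline) responses.
#'
#' @param trials a `trial_matrix` (needs >= 2 trials).
#' @param smooth_sd_ms Gaussian smoothing sigma in milliseconds.
#' @return An `snr_record`: list with `snr`, `response`, `noise`,
#'   `window` (`"onset"`, `"reversal"` or `"offset"`), `useful`
#'   (`snr > 1`), `valid` (`FALSE` with `snr = NA` when noise is zero).
#' @export
compute_snr <- function(trials, smooth_sd_ms = 5) {
  stopifnot(inherits(trials, "trial_matrix"))
  m <- trials$trials
  if (nrow(m) < 2L) stop("need at least 2 trials", call. = FALSE)
  tt <- trials$time_s
  base_idx <- which(tt >= -0.25 & tt < 0)
  if (length(base_idx) == 0L) stop("window lacks a baseline period",
                                   call. = FALSE)
  per_trial_base <- rowMeans(m[, base_idx, drop = FALSE])
  noise <- stats::sd(per_trial_base)
  mean_trace <- colMeans(m)
  mean_trace <- gaussian_smooth(mean_trace,
                                smooth_sd_ms / 1000 * trials$rate_hz)
  baseline <- mean(mean_trace[base_idx])
  wins <- list(onset = c(0, 0.25), reversal = c(0.5, 0.75),
               offset = c(1, 1.25))
  resp <- vapply(wins, function(w) {
    idx <- which(tt >= w[1] & tt <= w[2])
    if (length(idx) == 0L) return(NA_real_)
    max(abs(mean_trace[idx] - baseline))
  }, numeric(1))
  best <- names(which.max(resp))
  if (noise <= 0) {
    warning("zero baseline noise; SNR undefined for this electrode")
    return(structure(list(snr = NA_real_, response = unname(resp[best]),
                          noise = 0, window = best, useful = NA,
                          valid = FALSE),
                     class = "snr_record"))
  }
  snr <- unname(resp[best]) / noise
  structure(list(snr = snr, response = unname(resp[best]), noise = noise,
                 window = best, useful = snr > 1, valid = TRUE),
            class = "snr_record")
}

#' Process a raw recording into per-electrode SNR records
#'
#' Applies common-average referencing, extracts each electrode's MUA
#' envelope, decimates to 1 kHz, epochs around the stimulus onsets and
#' computes the SNR.
#'
#' @param rec a `raw_recording`.
#' @param car apply common-average referencing first.
#' @param material optional probe-material label carried into the output.
#' @param smooth_sd_ms passed to [compute_snr()].
#' @return Data frame with one row per electrode: `electrode`, `week`,
#'   `material`, `snr`, `window`, `useful`, `valid`.
#' @export
process_recording <- function(rec, car = TRUE, material = NA_character_,
                              smooth_sd_ms = 5) {
  stopifnot(inherits(rec, "raw_recording"))
  if (car && nrow(rec$samples) >= 2L) rec <- common_average_reference(rec)
  rows <- lapply(seq_len(nrow(rec$samples)), function(e) {
    env <- mua_envelope(rec$samples[e, ], rec$rate_hz)
    d <- decimate_envelope(env, rec$rate_hz, 1000)
    tm <- epoch_and_average(d$env, d$rate_hz, rec$onsets_s)
    s <- compute_snr(tm, smooth_sd_ms = smooth_sd_ms)
    data.frame(electrode = e, week = rec$week, material = material,
               snr = s$snr, window = s$window,
               useful = s$useful, valid = s$valid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Weekly aggregation of SNR records
#'
#' Averages multiple sessions within a week to one SNR per electrode-week,
#' derives the percentage of useful electrodes (SNR > 1) per material and
#' week, and assigns 4-week time bins for binned group comparisons.
#'
#' @param records data frame with columns `electrode`, `week`, `material`,
#'   `snr` (one row per electrode-session).
#' @param bin_weeks width of the time bins in weeks.
#' @return List with `weekly` (electrode x week mean SNR, plus `useful` and
#'   `time_bin`), and `fraction` (per material x week `pct_useful`).
#' @export
weekly_aggregate <- function(records, bin_weeks = 4) {
  stopifnot(all(c("electrode", "week", "material", "snr") %in%
                  names(records)))
  weekly <- stats::aggregate(snr ~ electrode + week + material,
                             data = records, FUN = mean)
  weekly$useful <- weekly$snr > 1
  weekly$time_bin <- floor((weekly$week - min(weekly$week)) / bin_weeks) + 1L
  fraction <- stats::aggregate(useful ~ material + week, data = weekly,
                               FUN = function(u) 100 * mean(u))
  names(fraction)[names(fraction) == "useful"] <- "pct_useful"
  list(weekly = weekly, fraction = fraction)
}
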