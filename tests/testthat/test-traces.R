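# Trace conditioning: zero-lag filters, smoothing, binarization, signalling
# parameters, response times, first responders.

make_ts <- function(x, fs = 10) {
  x <- as.matrix(x)
  new_trace_set(x, (seq_len(nrow(x)) - 1) / fs,
                cbind(seq_len(ncol(x)) * 15, 0), fs, 0)
}

test_that("band-pass removes DC and keeps in-band tones", {
  fs <- 10; n <- 4000
  t <- (0:(n - 1)) / fs
  ts <- make_ts(cbind(rep(5, n), sin(2 * pi * 0.3 * t)))
  out <- bandpass_zero_lag(ts, 0.03, 1)
  expect_lt(max(abs(out$values[, 1])), 1e-8)
  # FFT-gain oracle: a 0.3 Hz unit tone inside [0.03, 1] keeps >= 95 %
  expect_gte(tone_amplitude(out$values[, 2], 0.3, fs), 0.95)
})

test_that("filters are zero-lag and linear", {
  fs <- 10; n <- 2000
  t <- (0:(n - 1)) / fs
  pulse <- exp(-((t - 100)^2) / (2 * 4^2))
  out <- bandpass_zero_lag(make_ts(pulse), 0.03, 1)
  expect_lte(abs(which.max(out$values[, 1]) - which.max(pulse)), 1)
  set.seed(42)
  x <- rnorm(n); y <- rnorm(n)
  f <- function(v) bandpass_zero_lag(make_ts(v), 0.035, 1.5)$values[, 1]
  expect_lt(max(abs(f(2 * x - 3 * y) - (2 * f(x) - 3 * f(y)))), 1e-8)
})

test_that("high-pass removes ramps, keeps oscillations, preserves zero", {
  fs <- 10; n <- 6000
  t <- (0:(n - 1)) / fs
  ramp <- t / max(t)
  out <- highpass_zero_lag(make_ts(ramp), 0.01)
  interior <- 500:5500
  expect_lte(sd(out$values[interior, 1]), 0.05 * sd(ramp))
  tone <- sin(2 * pi * 0.1 * t)
  expect_gte(tone_amplitude(highpass_zero_lag(make_ts(tone), 0.01)$values[, 1],
                            0.1, fs), 0.95)
  expect_equal(highpass_zero_lag(make_ts(rep(0, n)), 0.01)$values[, 1],
               rep(0, n))
})

test_that("invalid cutoffs are rejected", {
  ts <- make_ts(rnorm(100))
  expect_error(bandpass_zero_lag(ts, 0.03, 6), "Nyquist")
  expect_error(bandpass_zero_lag(ts, 1, 0.5), "f_lo")
  expect_error(highpass_zero_lag(ts, -0.1), "Nyquist")
})

test_that("adjacent averaging matches the brute-force oracle", {
  expect_identical(smooth_adjacent(make_ts(c(0, 0, 3, 0, 0)), 3)$values[, 1],
                   c(0, 1, 1, 1, 0))
  x <- rnorm(200)
  expect_identical(smooth_adjacent(make_ts(x), 1)$values[, 1], x)
  sm <- smooth_adjacent(make_ts(x), 5)$values[, 1]
  oracle <- vapply(seq_along(x), function(i) {
    h <- min(2, i - 1, length(x) - i)  # shrinking centred window
    mean(x[(i - h):(i + h)])
  }, 0)
  expect_equal(sm, oracle, tolerance = 1e-12)
  expect_error(smooth_adjacent(make_ts(x), 4), "odd")
  expect_error(smooth_adjacent(make_ts(x), -1), "odd")
})

test_that("binarization handles flat traces, short spikes, square waves", {
  fs <- 10
  flat <- make_ts(rep(0, 200))
  expect_warning(ba <- binarize(flat), "flat")
  expect_true(all(ba$states == 0))
  expect_length(ba$onsets[[1]], 0)
  spike <- rep(0, 200); spike[100] <- 1
  ba2 <- suppressWarnings(binarize(make_ts(spike), min_dur_s = 0.3))
  expect_true(all(ba2$states == 0))
  # square wave: 12 pulses of 2 s in 120 s
  sq <- rep(rep(c(1, 0), 12), times = rep(c(20, 80), 12))
  ba3 <- binarize(make_ts(sq))
  p <- signaling_params(ba3, c(0, 120))
  expect_equal(p$active_time, 0.2)
  expect_equal(p$freq_hz, 0.1)
  expect_equal(p$dur_s, 2)
  # binarization is idempotent on its own reconstructed square wave
  ba4 <- binarize(make_ts(ba3$states + 0))
  expect_identical(ba4$states, ba3$states)
})

test_that("onsets and offsets alternate consistently with states", {
  gen <- get_islet(small_cfg(seed = 2))
  ba <- binarize(smooth_adjacent(
    bandpass_zero_lag(gen$traces, 0.035, 1.5), 5), min_dur_s = 1)
  for (i in c(1, 10, 25)) {
    on <- ba$onsets[[i]]; off <- ba$offsets[[i]]
    expect_length(off, length(on))
    expect_true(all(off > on))
    if (length(on) > 1) expect_true(all(on[-1] > off[-length(off)]))
    expect_equal(sum(ba$states[, i]) / ba$sampling_hz, sum(off - on))
  }
})

test_that("noiseless binarization recovers the truth to one frame per edge", {
  cfg <- small_cfg(seed = 5, noise_sd = 0, drift_amp = 0)
  gen <- generate_islet(cfg)
  ba <- binarize(gen$traces, theta_amp = 0.3, min_dur_s = 0.3)
  for (i in seq_len(ncol(ba$states))) {
    tru <- runs_of_ones_oracle(gen$truth$binary[, i])
    mismatch <- sum(ba$states[, i] != gen$truth$binary[, i])
    # each edge may be off by at most one frame (plus bridged 1-frame gaps)
    expect_lte(mismatch, 2 * nrow(tru) + 4)
    # every well-separated true run of >= 4 frames has a detected onset
    # within one frame (shorter runs may fall to the duration filter, and
    # one-frame gaps may be bridged)
    det_on <- ba$onsets[[i]]
    gap_ok <- c(TRUE, tru$start[-1] - tru$end[-nrow(tru)] > 2)
    long_ok <- tru$end - tru$start + 1 >= 4
    for (t_on in (tru$start[gap_ok & long_ok] - 1) * 0.1)
      expect_true(any(abs(det_on - t_on) <= 0.1 + 1e-9))
  }
})

test_that("signalling parameters flag zero-oscillation cells distinctly", {
  states <- cbind(rep(0L, 100), rep(1L, 100))
  ba <- ba_from_states(states)
  p <- suppressWarnings(signaling_params(ba, c(0, 10)))
  expect_equal(p$freq_hz[1], 0)
  expect_true(is.na(p$dur_s[1]))
  expect_equal(p$active_time[2], 1)
  expect_error(signaling_params(ba, c(5, 20)), "inside the recording")
})

test_that("response times locate constructed steps and flag non-responders", {
  fs <- 10; n <- 1500
  set.seed(7)
  base <- matrix(rnorm(n * 2, 0, 0.05), n, 2)
  step <- base
  i0 <- fs * (60 + 40) + 1  # frame whose timestamp is exactly 100 s
  step[i0:n, 1] <- step[i0:n, 1] + 10 * 0.05 * 10
  ts <- new_trace_set(step, (0:(n - 1)) / fs, cbind(1:2, 0), fs, 60)
  rt <- detect_response_time(ts, smooth_window = 1)
  expect_lt(abs(rt[1] - 40), 0.1 + 1e-9)
  expect_true(is.na(rt[2]))  # flat noise trace never crosses
  expect_error(detect_response_time(ts, stim_onset_s = 500), "outside")
  # manual override replaces detection
  rt2 <- detect_response_time(ts,
                              manual = data.frame(cell = 2,
                                                  response_time_s = 12))
  expect_identical(rt2, c(NA, 12))
})

test_that("first responders are the earliest ceiling(N/6) responders", {
  set.seed(1)
  rt <- sample(seq(1, 60, length.out = 120))
  fr <- first_responders(rt)
  expect_identical(sum(fr), 20L)
  expect_setequal(which(fr), order(rt)[1:20])
  rt10 <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  expect_identical(sum(first_responders(rt10)), 2L)
  expect_setequal(which(first_responders(rt10)), c(2, 6))
  # non-responders never flagged
  rt_na <- c(NA, NA, NA, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  expect_false(any(first_responders(rt_na)[1:3]))
  expect_error(first_responders(rep(NA_real_, 12)), "no responding")
})

test_that("frequency times window length equals the onset count", {
  gen <- get_islet(small_cfg(seed = 2))
  ba <- binarize(smooth_adjacent(
    bandpass_zero_lag(gen$traces, 0.035, 1.5), 5), min_dur_s = 1)
  win <- gen$truth$sustained_window
  p <- signaling_params(ba, win)
  expect_true(all(p$active_time >= 0 & p$active_time <= 1))
  counts <- vapply(ba$onsets, function(o) sum(o >= win[1] & o < win[2]), 0L)
  expect_equal(p$freq_hz * diff(win), as.numeric(counts))
})
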