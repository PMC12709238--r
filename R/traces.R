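# Trace conditioning and per-cell signalling parameters: zero-phase
# filtering, adjacent-averaging smoothing, binarization, active time /
# frequency / duration, response times and first-responder labels.

# Zero-phase frequency-domain filter. The signal is extended by even
# reflection (which removes the periodic-wraparound discontinuity), FFT'd,
# multiplied by the squared-magnitude response of an order-`order`
# Butterworth filter -- the same magnitude response a forward-backward
# time-domain Butterworth (filtfilt) would apply -- and inverse-transformed.
# Purely real gain means exactly zero phase shift at every frequency.
zp_filter_matrix <- function(x, fs, f_lo = NULL, f_hi = NULL, order = 4) {
  n <- nrow(x)
  xe <- rbind(x, x[n:1, , drop = FALSE])  # even extension, length 2n
  m <- 2L * n
  f <- (seq_len(m) - 1L) / m * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  gain <- rep(1, m)
  if (!is.null(f_hi)) gain <- gain / (1 + (f / f_hi)^(2 * order))
  if (!is.null(f_lo)) {
    hp <- ifelse(f == 0, 0, 1 / (1 + (f_lo / pmax(f, 1e-300))^(2 * order)))
    gain <- gain * hp
  }
  xf <- stats::mvfft(xe)
  out <- Re(stats::mvfft(xf * gain, inverse = TRUE)) / m
  out[seq_len(n), , drop = FALSE]
}

check_cutoffs <- function(fs, ...) {
  cuts <- c(...)
  nyq <- fs / 2
  if (any(cuts <= 0) || any(cuts >= nyq))
    stop("invalid cutoff: frequencies must lie in (0, Nyquist = ", nyq,
         " Hz), got ", paste(cuts, collapse = ", "))
  if (length(cuts) == 2 && cuts[1] >= cuts[2])
    stop("invalid cutoff: f_lo must be below f_hi")
}

#' Zero-lag band-pass filter
#'
#' Band-pass filters every trace with a zero-phase (forward-backward
#' equivalent) Butterworth response, removing baseline drift below `f_lo` and
#' noise above `f_hi`. Defaults are the midpoints of the mouse-mode cutoff
#' ranges: 0.035 Hz and 1.5 Hz.
#'
#' @param ts a `trace_set`.
#' @param f_lo,f_hi lower and upper cutoff (Hz), `0 < f_lo < f_hi < fs/2`.
#' @param order Butterworth order (default 4).
#' @return a `trace_set` with filtered values (same shape; DC removed).
#' @export
bandpass_zero_lag <- function(ts, f_lo = 0.035, f_hi = 1.5, order = 4) {
  assert_trace_set(ts)
  check_cutoffs(ts$sampling_hz, f_lo, f_hi)
  ts$values <- zp_filter_matrix(ts$values, ts$sampling_hz, f_lo, f_hi, order)
  ts
}

#' Zero-lag high-pass filter
#'
#' High-pass equivalent of [bandpass_zero_lag()], used for slow human-mode
#' recordings where only baseline drift must be removed. Default cutoff
#' 0.0075 Hz (midpoint of the 0.005-0.01 Hz range).
#'
#' @inheritParams bandpass_zero_lag
#' @param f_c cutoff frequency (Hz).
#' @export
highpass_zero_lag <- function(ts, f_c = 0.0075, order = 4) {
  assert_trace_set(ts)
  check_cutoffs(ts$sampling_hz, f_c)
  ts$values <- zp_filter_matrix(ts$values, ts$sampling_hz, f_lo = f_c,
                                order = order)
  ts
}

#' Adjacent-averaging smoothing
#'
#' Centred moving average with an odd window; windows shrink symmetrically at
#' the edges, and `window = 1` is the identity.
#'
#' @param ts a `trace_set`.
#' @param window odd positive window length in frames.
#' @export
smooth_adjacent <- function(ts, window = 5) {
  assert_trace_set(ts)
  ts$values <- apply(ts$values, 2L, smooth_vec, window = window)
  ts
}

smooth_vec <- function(x, window) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be an odd positive integer, got ", window)
  if (window == 1) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  # shrink symmetrically at edges so the window stays centred
  half <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - half
  hi <- seq_len(n) + half
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Binarize filtered traces into active / silent states
#'
#' Per cell, frames are active where the filtered signal exceeds
#' `median + theta_amp * (95th percentile - median)`, i.e. a fraction of the
#' robust oscillation amplitude above the baseline. Active runs shorter than
#' `min_dur_s` are removed, then silent gaps shorter than `min_dur_s / 2` are
#' bridged. Onset and offset times (the offset is the first silent frame
#' after a run) are derived from the final states. Cells with zero robust
#' amplitude are marked inactive with a warning.
#'
#' @param ts a filtered and smoothed `trace_set`.
#' @param theta_amp threshold as a fraction of the robust amplitude, in (0,1).
#' @param min_dur_s minimal oscillation duration (s); default 3 frames.
#' @return object of class `binary_activity` with elements `states`
#'   (time x cell 0/1 matrix), `onsets` and `offsets` (per-cell lists of
#'   times, s), and `time_s`.
#' @export
binarize <- function(ts, theta_amp = 0.3, min_dur_s = 3 / ts$sampling_hz) {
  assert_trace_set(ts)
  if (theta_amp <= 0 || theta_amp >= 1) stop("theta_amp must lie in (0, 1)")
  n <- ncol(ts$values)
  dtf <- 1 / ts$sampling_hz
  min_frames <- max(1L, round(min_dur_s * ts$sampling_hz))
  gap_frames <- max(1L, round(min_dur_s * ts$sampling_hz / 2))
  states <- matrix(0L, nrow(ts$values), n,
                   dimnames = list(NULL, colnames(ts$values)))
  flat <- logical(n)
  for (i in seq_len(n)) {
    x <- ts$values[, i]
    med <- stats::median(x)
    amp <- stats::quantile(x, 0.95, names = FALSE) - med
    if (amp <= .Machine$double.eps^0.5) { flat[i] <- TRUE; next }
    s <- as.integer(x > med + theta_amp * amp)
    s <- drop_short_runs(s, min_frames)
    s <- bridge_short_gaps(s, gap_frames)
    states[, i] <- s
  }
  if (any(flat))
    warning(sum(flat), " flat cell(s) (zero robust amplitude) marked inactive: ",
            paste(utils::head(which(flat), 5), collapse = ", "))
  onsets <- offsets <- vector("list", n)
  for (i in seq_len(n)) {
    r <- runs_of_ones(states[, i])
    onsets[[i]] <- ts$time_s[r$start]
    offsets[[i]] <- ts$time_s[r$end] + dtf
  }
  structure(list(states = states, onsets = onsets, offsets = offsets,
                 time_s = ts$time_s, sampling_hz = ts$sampling_hz),
            class = "binary_activity")
}

drop_short_runs <- function(s, min_frames) {
  r <- runs_of_ones(s)
  short <- r[r$end - r$start + 1L < min_frames, , drop = FALSE]
  for (k in seq_len(nrow(short))) s[short$start[k]:short$end[k]] <- 0L
  s
}

bridge_short_gaps <- function(s, gap_frames) {
  r <- runs_of_ones(1L - s)
  n <- length(s)
  # only interior gaps (bounded by activity on both sides) are bridged
  r <- r[r$start > 1L & r$end < n & r$end - r$start + 1L < gap_frames, ,
         drop = FALSE]
  for (k in seq_len(nrow(r))) s[r$start[k]:r$end[k]] <- 1L
  s
}

#' Per-cell signalling parameters from binarized activity
#'
#' Within the analysis window (normally the sustained phase):
#' relative active time = active frames / window frames; oscillation
#' frequency = number of onsets in the window / window length; mean
#' oscillation duration = mean offset-onset difference over oscillations
#' starting in the window (`NA` when a cell has none, distinct from 0).
#'
#' @param ba a `binary_activity`.
#' @param window numeric `c(t0, t1)` (s) inside the recording.
#' @param response_time_s optional per-cell response times from
#'   [detect_response_time()], carried into the result.
#' @return data.frame of class `signaling_params` with columns `cell`,
#'   `active_time`, `freq_hz`, `dur_s`, `response_time_s`.
#' @export
signaling_params <- function(ba, window, response_time_s = NULL) {
  stopifnot(inherits(ba, "binary_activity"), length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  if (t0 >= t1 || t0 < ba$time_s[1] - 1e-9 ||
      t1 > ba$time_s[length(ba$time_s)] + 1 / ba$sampling_hz + 1e-9)
    stop("analysis window must lie inside the recording")
  in_win <- ba$time_s >= t0 & ba$time_s < t1
  n <- ncol(ba$states)
  active_time <- colSums(ba$states[in_win, , drop = FALSE]) / sum(in_win)
  freq <- dur <- numeric(n)
  for (i in seq_len(n)) {
    sel <- ba$onsets[[i]] >= t0 & ba$onsets[[i]] < t1
    k <- sum(sel)
    freq[i] <- k / (t1 - t0)
    dur[i] <- if (k == 0L) NA_real_ else
      mean(ba$offsets[[i]][sel] - ba$onsets[[i]][sel])
  }
  out <- data.frame(cell = colnames(ba$states) %||% seq_len(n),
                    active_time = active_time, freq_hz = freq, dur_s = dur,
                    response_time_s = if (is.null(response_time_s))
                      NA_real_ else response_time_s)
  class(out) <- c("signaling_params", "data.frame")
  attr(out, "window") <- window
  out
}

#' Detect glucose response times
#'
#' Automated surrogate for manual onset picking: the response time of a cell
#' is the first time after the stimulus at which its smoothed trace exceeds
#' the pre-stimulus baseline median by `k_sd` baseline SDs continuously for
#' `hold_s`. Cells that never cross are flagged non-responders (`NA`).
#'
#' @param ts a `trace_set` (raw or mildly filtered).
#' @param stim_onset_s stimulation onset (s); defaults to the metadata value.
#' @param k_sd threshold in baseline SDs.
#' @param hold_s time (s) the signal must stay above threshold.
#' @param smooth_window odd smoothing window (frames) applied first.
#' @param manual optional manually curated onsets replacing the automated
#'   detection: a data.frame (or CSV path) with columns `cell` (index or
#'   name) and `response_time_s`; cells absent from it are non-responders.
#' @return numeric vector of response times in seconds after the stimulus
#'   (`NA` = non-responder).
#' @export
detect_response_time <- function(ts, stim_onset_s = ts$stim_onset_s,
                                 k_sd = 3, hold_s = 2, smooth_window = 5,
                                 manual = NULL) {
  assert_trace_set(ts)
  if (!is.null(manual)) {
    if (is.character(manual)) manual <- utils::read.csv(manual)
    stopifnot(all(c("cell", "response_time_s") %in% colnames(manual)))
    resp <- rep(NA_real_, ncol(ts$values))
    idx <- if (is.numeric(manual$cell)) manual$cell else
      match(manual$cell, colnames(ts$values))
    resp[idx] <- manual$response_time_s
    return(resp)
  }
  t_end <- ts$time_s[length(ts$time_s)]
  if (stim_onset_s <= ts$time_s[1] || stim_onset_s >= t_end)
    stop("stim_onset_s lies outside the recording")
  if (stim_onset_s - ts$time_s[1] < 30)
    warning("less than 30 s of pre-stimulus baseline; estimates may be noisy")
  hold_frames <- max(1L, round(hold_s * ts$sampling_hz))
  sm <- apply(ts$values, 2L, smooth_vec, window = smooth_window)
  base <- ts$time_s < stim_onset_s
  post <- which(ts$time_s >= stim_onset_s)
  resp <- rep(NA_real_, ncol(sm))
  for (i in seq_len(ncol(sm))) {
    thr <- stats::median(sm[base, i]) + k_sd * stats::sd(sm[base, i])
    above <- sm[post, i] > thr
    r <- runs_of_ones(above)
    r <- r[r$end - r$start + 1L >= hold_frames, , drop = FALSE]
    if (nrow(r) > 0L)
      resp[i] <- ts$time_s[post[r$start[1]]] - stim_onset_s
  }
  resp
}

#' Flag first-responder cells
#'
#' First responders are the top 1/6 of cells (exactly `ceiling(N/6)`) with
#' the shortest response times; non-responders are never flagged and ties are
#' broken by cell index.
#'
#' @param params a `signaling_params` data.frame (or a numeric vector of
#'   response times).
#' @return logical vector of flags.
#' @export
first_responders <- function(params) {
  rt <- if (is.numeric(params)) params else params$response_time_s
  if (all(is.na(rt))) stop("no responding cells; cannot flag first responders")
  top_fraction_flags(rt, decreasing = FALSE)
}
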