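#' Zero-phase IIR band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward
#' ([signal::filtfilt()]) so trial windows are not shifted by filter group
#' delay. Both EEG and EOG channels are filtered; events are untouched.
#' The two bands used in motor-imagery work, mu only (8-12 Hz) and the
#' broad sensorimotor band (8-30 Hz), are the common choices for `lo`/`hi`.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order (default 4).
#' @return the filtered `eeg_recording`.
#' @export
bandpass <- function(rec, lo, hi, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_num(lo, "lo", lo = 1e-9)
  assert_scalar_num(hi, "hi")
  if (!(lo < hi) || hi >= rec$fs / 2)
    stop_config("band must satisfy 0 < lo < hi < fs/2; got [", lo, ", ", hi,
                "] at fs = ", rec$fs)
  flt <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- .filtfilt_mat(flt$b, flt$a, rec$data)
  out
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (constrained biquad with pole radius `r`),
#' applied forward-backward. With the default `r = 0.97` at 250 Hz the
#' stop band is narrow: essentially complete rejection at the notch
#' frequency and under 1 dB of ripple 5 Hz away.
#'
#' @param rec an `eeg_recording`.
#' @param freq notch centre in Hz (line frequency, typically 50).
#' @param r pole radius in (0, 1); closer to 1 gives a narrower notch.
#' @return the filtered `eeg_recording`.
#' @export
notch <- function(rec, freq = 50, r = 0.97) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_num(freq, "freq", lo = 1e-9)
  assert_scalar_num(r, "r", lo = 1e-6, hi = 1 - 1e-9)
  if (freq >= rec$fs / 2)
    stop_config("notch frequency ", freq, " must be below fs/2 = ", rec$fs / 2)
  flt <- notch_filter(freq, rec$fs, r)
  out <- rec
  out$data <- .filtfilt_mat(flt$b, flt$a, rec$data)
  out
}

## biquad notch: zeros on the unit circle at +-w0, poles at radius r;
## normalized to unit gain at DC
notch_filter <- function(freq, fs, r) {
  w0 <- 2 * pi * freq / fs
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  g <- sum(a) / sum(b)
  signal::Arma(b = b * g, a = a)
}

#' Cut labeled trials around cue events
#'
#' Extracts one trial per event using a half-open window
#' `[cue + window[1], cue + window[2])` in seconds relative to the cue
#' sample. The default window 0.5-2.5 s post-cue is the conventional
#' motor-imagery epoch.
#'
#' @param rec an `eeg_recording`.
#' @param window length-2 numeric, start and end offset in seconds.
#' @return a `trial_tensor`: list with `trials` (trial x channel x sample
#'   array), `labels`, `fs`, and `window`.
#' @export
epoch <- function(rec, window = c(0.5, 2.5)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(window) != 2 || !(window[1] < window[2]))
    stop_config("window must be (start, end) seconds with start < end")
  ev <- rec$events
  n_sm <- ncol(rec$data)
  off0 <- round(window[1] * rec$fs)
  off1 <- round(window[2] * rec$fs)
  len <- off1 - off0
  if (len < 1) stop_config("window shorter than one sample at fs = ", rec$fs)
  if (nrow(ev)) {
    starts <- ev$sample + off0
    ends <- starts + len - 1L
    bad <- which(starts < 1L | ends > n_sm)
    if (length(bad))
      stop_config("epoch window exceeds recording bounds for events: ",
                  paste(bad, collapse = ", "))
  }
  trials <- array(0, dim = c(nrow(ev), nrow(rec$data), len))
  for (i in seq_len(nrow(ev))) {
    s <- ev$sample[i] + off0
    trials[i, , ] <- rec$data[, s:(s + len - 1L), drop = FALSE]
  }
  structure(list(trials = trials, labels = ev$label, fs = rec$fs,
                 window = window),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_tensor> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  if (d[1]) cat("  labels:", paste(sprintf("%d:%d", sort(unique(x$labels)),
                                           tabulate(x$labels)[sort(unique(x$labels))]),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Keep only a subset of channels
#' @param rec an `eeg_recording`.
#' @param idx integer channel indices to keep.
#' @return an `eeg_recording` with the selected channels.
#' @export
select_channels <- function(rec, idx) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (any(idx < 1 | idx > nrow(rec$data))) stop_config("channel index out of range")
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs,
                rec$channel_names[idx], rec$channel_types[idx], rec$events)
}
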