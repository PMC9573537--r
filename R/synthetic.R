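#' Describe one latent source of the synthetic EEG model
#'
#' Sources are amplitude-modulated narrowband oscillations (mu/beta
#' rhythms), 1/f background noise, sparse ocular blink pulses, or mains
#' line noise. Motor-imagery class structure enters through `class_gain`:
#' during trials of class `k` the source envelope is multiplied by
#' `class_gain[k]`, so event-related desynchronization (ERD) is a gain
#' below 1 for that class.
#'
#' @param kind one of `"mu_rhythm"`, `"beta_rhythm"`, `"pink_noise"`,
#'   `"eog_blink"`, `"line_noise"`.
#' @param center_freq oscillation centre in Hz (ignored for `pink_noise`
#'   and `eog_blink`; forced to 50 for `line_noise`).
#' @param class_gain numeric vector of per-class linear gains (> 0),
#'   recycled to the number of classes; `1` means no modulation.
#' @param amplitude target RMS amplitude in microvolts.
#' @return a `source_spec` list.
#' @export
source_spec <- function(kind = c("mu_rhythm", "beta_rhythm", "pink_noise",
                                 "eog_blink", "line_noise"),
                        center_freq = NULL, class_gain = 1, amplitude = 10) {
  kind <- match.arg(kind)
  if (is.null(center_freq))
    center_freq <- switch(kind, mu_rhythm = 10, beta_rhythm = 20,
                          line_noise = 50, pink_noise = NA_real_,
                          eog_blink = NA_real_)
  if (kind == "line_noise") center_freq <- 50
  if (kind %in% c("mu_rhythm", "beta_rhythm", "line_noise"))
    assert_scalar_num(center_freq, "center_freq", lo = 1e-9)
  if (any(!is.finite(class_gain)) || any(class_gain <= 0))
    stop_config("class_gain values must be positive and finite")
  assert_scalar_num(amplitude, "amplitude", lo = 1e-12)
  structure(list(kind = kind, center_freq = center_freq,
                 class_gain = class_gain, amplitude = amplitude),
            class = "source_spec")
}

#' Simulation configuration
#'
#' Defaults mirror a standard four-class motor-imagery montage: 22 EEG +
#' 3 EOG channels sampled at 250 Hz, 4 s imagery trials separated by 2 s
#' of rest.
#'
#' @param n_eeg_channels,n_eog_channels channel counts.
#' @param fs sampling rate, Hz.
#' @param n_trials_per_class trials per class.
#' @param trial_sec,rest_sec trial and inter-trial durations in seconds.
#' @param n_classes number of motor-imagery classes.
#' @param snr_db sensor-noise SNR in dB relative to the mixed neural
#'   signal; `Inf` disables sensor noise.
#' @param drift_rate per-second Frobenius-norm rate of mixing-matrix
#'   change (0 = stationary mixing).
#' @param cond_cap maximum allowed condition number of the mixing matrix.
#' @param t_start simulation start time in seconds (lets a second session
#'   continue an ongoing mixing drift).
#' @param seed integer RNG seed for source realizations, trial order, and
#'   sensor noise.
#' @param mixing_seed seed for the mixing matrix and drift direction;
#'   defaults to `seed`. Two sessions of the same simulated subject share
#'   `mixing_seed` (same head and montage) while differing in `seed`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_eeg_channels = 22, n_eog_channels = 3, fs = 250,
                       n_trials_per_class = 12, trial_sec = 4, rest_sec = 2,
                       n_classes = 4, snr_db = 10, drift_rate = 0,
                       cond_cap = 30, t_start = 0, seed = 1,
                       mixing_seed = NULL) {
  cfg <- list(
    n_eeg_channels = assert_count(n_eeg_channels, "n_eeg_channels"),
    n_eog_channels = assert_count(n_eog_channels, "n_eog_channels", min = 0L),
    fs = assert_scalar_num(fs, "fs", lo = 1),
    n_trials_per_class = assert_count(n_trials_per_class, "n_trials_per_class"),
    trial_sec = assert_scalar_num(trial_sec, "trial_sec", lo = 1e-3),
    rest_sec = assert_scalar_num(rest_sec, "rest_sec", lo = 0),
    n_classes = assert_count(n_classes, "n_classes"),
    snr_db = if (is.infinite(snr_db)) Inf else assert_scalar_num(snr_db, "snr_db"),
    drift_rate = assert_scalar_num(drift_rate, "drift_rate", lo = 0),
    cond_cap = assert_scalar_num(cond_cap, "cond_cap", lo = 1),
    t_start = assert_scalar_num(t_start, "t_start", lo = 0),
    seed = assert_count(seed, "seed", min = 0L),
    mixing_seed = assert_count(mixing_seed %||% seed, "mixing_seed", min = 0L)
  )
  structure(cfg, class = "sim_config")
}

#' Default source set for a four-class simulation
#'
#' One mu-rhythm source per class carrying that class's ERD (envelope gain
#' `erd_gain` during its own trials, 1 elsewhere), a beta-rhythm source
#' with mild ERD for class 1, a pink-noise background, one blink source,
#' and 50 Hz line noise.
#'
#' @param n_classes number of classes.
#' @param erd_gain ERD envelope gain in (0, 1]; band power during the
#'   attenuated class scales by `erd_gain^2`.
#' @return list of `source_spec`.
#' @export
default_sources <- function(n_classes = 4, erd_gain = 0.4) {
  centers <- c(10, 11, 9.5, 10.5, 12, 9)[seq_len(n_classes)]
  specs <- lapply(seq_len(n_classes), function(k) {
    g <- rep(1, n_classes); g[k] <- erd_gain
    source_spec("mu_rhythm", center_freq = centers[k], class_gain = g,
                amplitude = 10)
  })
  g1 <- rep(1, n_classes); g1[1] <- sqrt(erd_gain)
  c(specs, list(
    source_spec("beta_rhythm", center_freq = 22, class_gain = g1, amplitude = 5),
    source_spec("pink_noise", amplitude = 8),
    source_spec("eog_blink", amplitude = 150),
    source_spec("line_noise", amplitude = 6)
  ))
}

#' Random well-conditioned mixing matrix
#'
#' Draws a Gaussian matrix and clamps its singular values so the condition
#' number does not exceed `cond_cap`; deterministic for a fixed seed.
#'
#' @param n_channels,n_sources dimensions, `n_channels >= n_sources >= 2`.
#' @param seed integer seed.
#' @param cond_cap maximum condition number.
#' @return `n_channels` x `n_sources` matrix of full column rank.
#' @export
make_mixing_matrix <- function(n_channels, n_sources, seed = 1, cond_cap = 10) {
  n_channels <- assert_count(n_channels, "n_channels", min = 2L)
  n_sources <- assert_count(n_sources, "n_sources", min = 2L)
  if (n_sources > n_channels)
    stop_config("n_sources (", n_sources, ") may not exceed n_channels (",
                n_channels, ")")
  assert_scalar_num(cond_cap, "cond_cap", lo = 1)
  A <- with_seed(seed, matrix(rnorm(n_channels * n_sources), n_channels))
  clamp_condition(A, cond_cap)
}

clamp_condition <- function(A, cond_cap) {
  sv <- svd(A)
  d <- pmax(sv$d, max(sv$d) / cond_cap)
  sv$u %*% (d * t(sv$v))
}

#' Smoothly drifted mixing matrix
#'
#' Models slow nonstationarity of the volume-conduction mixing: the matrix
#' moves linearly along a fixed random unit-Frobenius-norm direction, so
#' `||A(t) - A(0)||_F = drift_rate * t` exactly.
#'
#' @param A base mixing matrix (the state at `t = 0`).
#' @param t elapsed time in seconds.
#' @param drift_rate Frobenius-norm change per second (0 returns `A`).
#' @param seed seed fixing the drift direction.
#' @return the drifted matrix.
#' @export
drift_mixing <- function(A, t, drift_rate, seed = 1) {
  assert_scalar_num(drift_rate, "drift_rate", lo = 0)
  assert_scalar_num(t, "t", lo = 0)
  if (drift_rate == 0 || t == 0) return(A)
  D <- with_seed(derive_seed(seed, "drift"),
                 matrix(rnorm(length(A)), nrow(A)))
  D <- D / sqrt(sum(D^2))
  A + drift_rate * t * D
}

## one realized source waveform; envelope handling makes narrowband sources
## super-Gaussian (amplitude-modulated) as ICA's contrast presumes
gen_source <- function(spec, n, fs, trial_mask) {
  t <- seq_len(n) / fs
  x <- switch(spec$kind,
    mu_rhythm = ,
    beta_rhythm = {
      carrier <- narrowband_noise(n, fs, spec$center_freq)
      env <- burst_envelope(n, fs)
      gain <- rep(1, n)
      in_trial <- trial_mask > 0L
      gain[in_trial] <- spec$class_gain[trial_mask[in_trial]]
      carrier * env * gain
    },
    pink_noise = pink_noise(n),
    eog_blink = blink_train(n, fs),
    line_noise = sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
  )
  rms <- sqrt(mean(x^2))
  if (rms < 1e-12) rms <- 1
  x / rms * spec$amplitude
}

narrowband_noise <- function(n, fs, f0) {
  half <- max(1, min(f0 - 0.5, 1.5))
  band <- c(max(f0 - half, 0.5), min(f0 + half, fs / 2 - 0.5)) / (fs / 2)
  flt <- signal::butter(2, band, type = "pass")
  as.numeric(signal::filtfilt(flt, rnorm(n)))
}

## slowly varying positive envelope; the chi-squared term gives the
## modulated oscillation moderate super-Gaussian tails (kurtosis ~ 8)
## without making short-window power estimates wildly unstable
burst_envelope <- function(n, fs) {
  cutoff <- min(0.5, fs / 4) / (fs / 2)
  lp <- signal::butter(2, cutoff, type = "low")
  g <- as.numeric(signal::filtfilt(lp, rnorm(n)))
  g <- g / max(sqrt(mean(g^2)), 1e-12)
  1 + 0.5 * g^2
}

pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  X <- W / sqrt(f)
  Re(fft(X, inverse = TRUE)) / n
}

## each blink: slow lid-closure pulse plus a fast eyelid transient, so the
## ocular artifact carries energy into the mu band the way real blinks and
## saccades do (their sharp edges overlap the motor-imagery band)
blink_train <- function(n, fs, rate = 0.25, width = 0.05, edge_width = 0.012,
                        edge_frac = 0.6) {
  x <- numeric(n)
  dur <- n / fs
  k <- rpois(1, rate * dur)
  if (k == 0) k <- 1
  centers <- sort(runif(k, 0, dur))
  half <- ceiling(4 * width * fs)
  for (c0 in centers) {
    amp <- runif(1, 0.8, 1.2)
    mid <- round(c0 * fs)
    idx <- max(1, mid - half):min(n, mid + half)
    tt <- idx / fs - c0
    pulse <- exp(-tt^2 / (2 * width^2))
    edge <- -tt / edge_width * exp(0.5 - tt^2 / (2 * edge_width^2))
    x[idx] <- x[idx] + amp * (pulse + edge_frac * edge)
  }
  x
}

#' Simulate a motor-imagery EEG recording with known ground truth
#'
#' Lays out `n_trials_per_class` trials per class in seeded random order
#' (each `trial_sec` of imagery preceded by `rest_sec` of rest, cue event
#' at trial onset), realizes every source waveform with its per-class ERD
#' gain applied, mixes them through a full-column-rank matrix (blink
#' loading dominantly on the EOG channels with leakage into EEG channels),
#' adds white sensor noise at `snr_db`, and optionally drifts the mixing
#' over time.
#'
#' @param config a [sim_config()].
#' @param sources list of [source_spec()]; defaults to
#'   [default_sources()] for `config$n_classes`.
#' @return list with `recording` (an `eeg_recording`) and `ground_truth`
#'   (list: `A` base mixing, `A_segments` per-second mixing if drifting,
#'   `S` sources x samples, `noise`, `labels`, `artifact_source_indices`).
#' @export
simulate_recording <- function(config, sources = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sources)) sources <- default_sources(config$n_classes)
  if (length(sources) == 0) stop_config("source list must not be empty")
  if (!all(vapply(sources, inherits, TRUE, "source_spec")))
    stop_config("sources must be source_spec objects")
  neural <- vapply(sources, function(s)
    s$kind %in% c("mu_rhythm", "beta_rhythm"), TRUE)
  modulated <- vapply(sources, function(s)
    any(abs(s$class_gain - 1) > 1e-12), TRUE)
  if (config$n_classes > 1 && !any(neural & modulated))
    stop_config("need at least one neural source with class_gain != 1, ",
                "otherwise classes are indistinguishable")
  for (s in sources)
    if (s$kind %in% c("mu_rhythm", "beta_rhythm", "line_noise") &&
        s$center_freq >= config$fs / 2)
      stop_config("source centre frequency ", s$center_freq,
                  " exceeds Nyquist at fs = ", config$fs)

  fs <- config$fs
  n_trials <- config$n_trials_per_class * config$n_classes
  trial_len <- round(config$trial_sec * fs)
  rest_len <- round(config$rest_sec * fs)
  n <- n_trials * (trial_len + rest_len) + rest_len
  n_src <- length(sources)
  n_ch <- config$n_eeg_channels + config$n_eog_channels

  with_seed(config$seed, {
    labels <- sample(rep(seq_len(config$n_classes), config$n_trials_per_class))
    onsets <- rest_len + (seq_len(n_trials) - 1L) * (trial_len + rest_len) + 1L
    trial_mask <- integer(n)
    for (i in seq_len(n_trials))
      trial_mask[onsets[i]:(onsets[i] + trial_len - 1L)] <- labels[i]

    S <- matrix(0, n_src, n)
    for (j in seq_len(n_src))
      S[j, ] <- gen_source(sources[[j]], n, fs, trial_mask)

    A <- with_seed(derive_seed(config$mixing_seed, "mixing"),
                   structured_mixing(config, sources))
    artifact_idx <- which(vapply(sources, function(s)
      s$kind %in% c("eog_blink", "line_noise"), TRUE))

    ## mix, with per-second piecewise mixing drift when requested
    if (config$drift_rate > 0) {
      seg_len <- as.integer(fs)
      starts <- seq(1L, n, by = seg_len)
      X <- matrix(0, n_ch, n)
      A_segments <- vector("list", length(starts))
      for (si in seq_along(starts)) {
        s0 <- starts[si]
        s1 <- min(s0 + seg_len - 1L, n)
        t_mid <- config$t_start + (s0 + s1) / 2 / fs
        Ai <- drift_mixing(A, t_mid, config$drift_rate, config$mixing_seed)
        A_segments[[si]] <- list(start = s0, end = s1, A = Ai)
        X[, s0:s1] <- Ai %*% S[, s0:s1, drop = FALSE]
      }
    } else {
      X <- A %*% S
      A_segments <- NULL
    }

    ## white sensor noise scaled against the mixed neural signal
    if (is.finite(config$snr_db)) {
      neural_mix <- A[, neural, drop = FALSE] %*% S[neural, , drop = FALSE]
      p_sig <- mean(neural_mix^2)
      sigma <- sqrt(p_sig / 10^(config$snr_db / 10))
      noise <- matrix(rnorm(n_ch * n, sd = sigma), n_ch)
    } else {
      noise <- matrix(0, n_ch, n)
    }
    X <- X + noise

    ch_names <- c(sprintf("EEG%02d", seq_len(config$n_eeg_channels)),
                  if (config$n_eog_channels)
                    sprintf("EOG%02d", seq_len(config$n_eog_channels)))
    ch_types <- c(rep("EEG", config$n_eeg_channels),
                  rep("EOG", config$n_eog_channels))
    rec <- eeg_recording(X, fs, ch_names, ch_types,
                         events = data.frame(sample = onsets, label = labels))
    list(recording = rec,
         ground_truth = list(A = A, A_segments = A_segments, S = S,
                             noise = noise, labels = labels,
                             artifact_source_indices = artifact_idx,
                             trial_mask = trial_mask))
  })
}

## mixing with physiologically-flavoured structure: blink loads on EOG
## channels strongly and leaks mildly into EEG; neural sources load on EEG
structured_mixing <- function(config, sources) {
  n_eeg <- config$n_eeg_channels
  n_eog <- config$n_eog_channels
  n_src <- length(sources)
  kinds <- vapply(sources, function(s) s$kind, "")
  A <- matrix(rnorm(n_eeg * n_src), n_eeg)
  blink <- which(kinds == "eog_blink")
  line <- which(kinds == "line_noise")
  if (length(blink)) A[, blink] <- rnorm(n_eeg * length(blink), sd = 0.3)
  if (length(line)) A[, line] <- rnorm(n_eeg * length(line), mean = 0.4, sd = 0.2)
  if (n_eog > 0) {
    Ae <- matrix(rnorm(n_eog * n_src, sd = 0.1), n_eog)
    if (length(blink))
      Ae[, blink] <- 2 + matrix(abs(rnorm(n_eog * length(blink), sd = 0.3)), n_eog)
    A <- rbind(A, Ae)
  }
  if (n_src >= 2) clamp_condition(A, config$cond_cap) else A
}

#' Write ground truth alongside a recording bundle
#'
#' Stores the mixing matrix, sources, and artifact source indices as plain
#' text next to a bundle written by [write_bundle()], for test use.
#'
#' @param gt ground-truth list from [simulate_recording()].
#' @param dir bundle directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(gt$A, file.path(dir, "mixing.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(gt$S, file.path(dir, "sources.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(artifact_source_indices = gt$artifact_source_indices,
         labels = gt$labels),
    file.path(dir, "ground_truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
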