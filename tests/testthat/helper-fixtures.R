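# shared fixtures, built in code

# iid Laplace sources: unit variance, kurtosis 6 -- an easy super-Gaussian
# test bed for source separation
laplace_sources <- function(n_src, n, seed) {
  set.seed(seed)
  matrix(rexp(n_src * n) * sign(runif(n_src * n) - 0.5), n_src) / sqrt(2)
}

# square mixture of Laplace sources at a given sensor SNR
laplace_mixture <- function(n_src, n, seed, snr_db = 20, cond_cap = 10) {
  S <- laplace_sources(n_src, n, seed)
  A <- make_mixing_matrix(n_src, n_src, seed = seed, cond_cap = cond_cap)
  M <- A %*% S
  X <- M + matrix(rnorm(n_src * n, sd = sqrt(mean(M^2) / 10^(snr_db / 10))),
                  n_src)
  list(X = X, A = A, S = S)
}

# deterministic two-channel trial tensor whose class covariances are exactly
# diagonal: channel amplitudes a1, a2 on orthogonal square waves
diag_cov_trials <- function(a_class1 = c(2, 1), a_class2 = c(1, 2),
                            n_trials = 4, len = 64) {
  w1 <- rep(c(1, -1), length.out = len)
  w2 <- rep(c(1, 1, -1, -1), length.out = len)
  trials <- array(0, dim = c(2 * n_trials, 2, len))
  labels <- integer(2 * n_trials)
  for (i in seq_len(n_trials)) {
    trials[i, 1, ] <- a_class1[1] * w1
    trials[i, 2, ] <- a_class1[2] * w2
    labels[i] <- 1L
    trials[n_trials + i, 1, ] <- a_class2[1] * w1
    trials[n_trials + i, 2, ] <- a_class2[2] * w2
    labels[n_trials + i] <- 2L
  }
  structure(list(trials = trials, labels = labels, fs = 250,
                 window = c(0, len / 250)),
            class = "trial_tensor")
}

# two well-separated Gaussian blobs (or K blobs on a circle)
gaussian_blobs <- function(n_per_class, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  K <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(n_per_class * ncol(centers), sd = sd), n_per_class),
          2, centers[k, ], `+`)))
  list(x = X, y = rep(seq_len(K), each = n_per_class))
}

# small synthetic recording for IO / artifact tests
small_recording <- function(seed = 1, n_trials_per_class = 6, n_eeg = 6,
                            n_eog = 1, ...) {
  cfg <- sim_config(n_eeg_channels = n_eeg, n_eog_channels = n_eog,
                    n_trials_per_class = n_trials_per_class, seed = seed, ...)
  simulate_recording(cfg, default_sources(cfg$n_classes, 0.4))
}

# per-subject benchmark tables shipped with the package
extdata_table <- function(name) {
  path <- system.file("extdata", name, package = "bcidecode")
  stopifnot(nzchar(path))
  read.csv(path, row.names = 1, check.names = FALSE)
}
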