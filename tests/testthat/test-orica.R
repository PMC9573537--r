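test_that("state initialization and configuration validation", {
  st <- orica_init(4)
  expect_equal(st$X, diag(4))
  expect_equal(st$W, diag(4))
  expect_equal(st$i, 0L)
  expect_error(orica_init(1), "n_channels")
  expect_error(forgetting_schedule(u0 = 1.5), "u0")
  expect_error(forgetting_schedule(u0 = 0.2, u_min = 0.3), "u_min")
  expect_error(orica_init(4, block_size = 0), "block_size")
})

test_that("the forgetting schedule anneals to its floor", {
  sch <- forgetting_schedule(0.2, 0.6, 1e-4)
  u <- sch$u(0:10000)
  expect_equal(u[1], 0.2)
  expect_true(all(diff(u) <= 0))
  expect_true(all(u >= 1e-4 & u < 1))
  expect_equal(sch$u(1e9), 1e-4)
})

test_that("whitening update reproduces the hand-evaluated rank-one step", {
  ## x = (1,0)', X = I, u = 0.5: v = x, v'v = 1, denominator 1,
  ## X' = I + 1 * (I - diag(1, 0)) = diag(1, 2)
  st <- orica_init(2, schedule = forgetting_schedule(0.5, 0, 1e-6))
  st2 <- whiten_update(st, matrix(c(1, 0), 2, 1))
  expect_equal(st2$X, diag(c(1, 2)), tolerance = 1e-12)
  expect_equal(st2$i, 1L)
})

test_that("vanishing forgetting factor freezes the whitener", {
  eps <- 1e-9
  st <- orica_init(3, schedule = forgetting_schedule(2 * eps, 0, eps))
  set.seed(31)
  st2 <- whiten_update(st, matrix(rnorm(3 * 8), 3))
  expect_lt(max(abs(st2$X - diag(3))), 1e-6)
})

test_that("whitened output covariance converges to the identity", {
  set.seed(32)
  A <- make_mixing_matrix(4, 4, seed = 32, cond_cap = 8)
  X <- A %*% matrix(rnorm(4 * 10000), 4)
  st <- orica_init(4)
  for (s0 in seq(1, 10000, by = 8)) {
    blk <- X[, s0:min(s0 + 7, 10000), drop = FALSE]
    st <- whiten_update(st, blk)
  }
  v <- st$X %*% X[, 7501:10000]
  R <- stats::cov2cor(stats::cov(t(v)))
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
})

test_that("gradient-rule fixed points leave the demixer unchanged", {
  ## lr = 0: no learning
  st <- orica_init(2, rule = "gradient", lr = 0, activation = "tanh")
  st$last_u <- 0.1
  v <- matrix(rnorm(2 * 8), 2)
  expect_equal(demix_update(st, v)$W, diag(2))
  ## block with f(a) a' averaging to the identity: tanh(c) * c / 2 = 1
  cstar <- uniroot(function(c) tanh(c) * c / 2 - 1, c(1, 3), tol = 1e-14)$root
  blk <- cbind(c(cstar, 0), c(0, cstar), c(-cstar, 0), c(0, -cstar))
  st2 <- orica_init(2, rule = "gradient", lr = 0.5, activation = "tanh")
  st2$last_u <- 0.1
  expect_equal(demix_update(st2, blk)$W, diag(2), tolerance = 1e-9)
})

test_that("non-finite inputs and divergence raise informative errors", {
  st <- orica_init(2)
  expect_error(whiten_update(st, matrix(c(NA, 1), 2, 1)), "non-finite")
  expect_error(demix_update(st, matrix(c(Inf, 1), 2, 1)), "non-finite")
  expect_error(orica_process(st, matrix(c(1, NaN, 0, 1), 2)), "non-finite")
})

test_that("process iterates once per block including the trailing partial", {
  set.seed(33)
  X <- matrix(rnorm(3 * 103), 3)
  st <- orica_init(3, block_size = 8)
  res <- orica_process(st, X)
  expect_equal(res$state$i, as.integer(ceiling(103 / 8)))
  expect_equal(dim(res$activations), c(3L, 103L))
  ## one batch-like step
  st1 <- orica_init(3, block_size = 103)
  expect_equal(orica_process(st1, X)$state$i, 1L)
})

test_that("a second pass does not degrade separation", {
  better <- 0L
  for (seed in 1:10) {
    mix <- laplace_mixture(4, 8000, seed = 100 + seed)
    st <- orica_init(4)
    r1 <- orica_process(st, mix$X)
    a1 <- amari_index(r1$state$W %*% r1$state$X, mix$A)
    r2 <- orica_process(r1$state, mix$X)
    a2 <- amari_index(r2$state$W %*% r2$state$X, mix$A)
    if (a2 <= a1 + 1e-9) better <- better + 1L
  }
  expect_gte(better, 8L)
})

test_that("channel permutation leaves separation quality invariant", {
  mix <- laplace_mixture(4, 15000, seed = 41)
  P <- diag(4)[c(3, 1, 4, 2), ]
  run <- function(X) {
    st <- orica_init(4)
    r <- orica_process(st, X)
    r$state$W %*% r$state$X
  }
  a_orig <- amari_index(run(mix$X), mix$A)
  a_perm <- amari_index(run(P %*% mix$X), P %*% mix$A)
  expect_equal(a_orig, a_perm, tolerance = 1e-8)
})

test_that("Amari index is zero exactly for scaled permutations", {
  A <- make_mixing_matrix(3, 3, seed = 42)
  expect_equal(amari_index(solve(A), A), 0, tolerance = 1e-12)
  P <- diag(c(2, -1, 0.5))[c(2, 3, 1), ]
  expect_equal(amari_index(P %*% solve(A), A), 0, tolerance = 1e-12)
  expect_error(amari_index(matrix(1, 2, 3), matrix(1, 3, 3)), "square")
})

test_that("Amari index agrees with an independently coded evaluation", {
  ## second implementation, written directly from the definition
  amari2 <- function(P) {
    P <- abs(P); n <- nrow(P); tot <- 0
    for (i in 1:n) tot <- tot + sum(P[i, ]) / max(P[i, ]) - 1
    for (j in 1:n) tot <- tot + sum(P[, j]) / max(P[, j]) - 1
    tot / (2 * n * (n - 1))
  }
  P <- matrix(c(1, 0, 1, 1), 2)
  expect_equal(amari_index(P, diag(2)), amari2(P))
  expect_equal(amari2(P), 0.5)
  set.seed(43)
  for (i in 1:5) {
    M <- matrix(rnorm(16), 4)
    expect_equal(amari_index(M, diag(4)), amari2(M), tolerance = 1e-12)
  }
})

test_that("row renormalization keeps demixing row norms bounded", {
  mix <- laplace_mixture(4, 20000, seed = 44)
  st <- orica_init(4, renormalize = TRUE)
  res <- orica_process(st, mix$X)
  rn <- sqrt(rowSums(res$state$W^2))
  expect_true(all(rn > 1e-3 & rn < 1e3))
  expect_equal(rn, rep(1, 4), tolerance = 1e-12)
})

test_that("components matching an EOG channel are always flagged", {
  sim <- small_recording(seed = 45, n_trials_per_class = 3)
  rec <- sim$recording
  acts <- rbind(rnorm(ncol(rec$data)),
                rec$data[eog_channels(rec)[1], ])
  expect_equal(flag_artifact_components(acts, rec, corr_threshold = 0.95), 2L)
  ## unreachable threshold and no line noise: empty set
  rec_nl <- notch(rec, 50)
  acts_nl <- matrix(rnorm(2 * ncol(rec$data)), 2)
  expect_length(
    flag_artifact_components(acts_nl, rec_nl, corr_threshold = 1), 0)
  ## without EOG channels the ocular criterion is skipped with a warning
  rec_eeg <- select_channels(rec, eeg_channels(rec))
  expect_warning(flag_artifact_components(acts_nl, rec_eeg), "EOG")
})

test_that("known blink sources are flagged across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    sim <- small_recording(seed = 200 + seed, n_trials_per_class = 6,
                           n_eeg = 6, n_eog = 1)
    rec <- notch(sim$recording, 50)
    st <- orica_init(7)
    res <- orica_process(st, rec)
    res <- orica_process(res$state, rec)  # convergence pass
    fl <- flag_artifact_components(res$activations, rec,
                                   corr_threshold = 0.3)
    if (length(fl) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("back-projection with nothing rejected is the identity", {
  mix <- laplace_mixture(4, 4000, seed = 46)
  rec <- eeg_recording(mix$X, 250)
  st <- orica_init(4)
  res <- orica_process(st, rec)
  clean <- reconstruct_clean(rec, res$state, integer(0))
  expect_lt(max(abs(clean$data - rec$data)) / stats::sd(rec$data), 1e-6)
  ## rejecting everything leaves (almost) nothing
  none <- reconstruct_clean(rec, res$state, 1:4)
  expect_lt(stats::sd(none$data) / stats::sd(rec$data), 0.05)
  expect_error(reconstruct_clean(rec, res$state, 5), "range")
})

test_that("rejecting the flagged blink halves EOG-linked EEG variance", {
  sim <- small_recording(seed = 47, n_trials_per_class = 6, n_eeg = 6,
                         n_eog = 1)
  rec <- notch(sim$recording, 50)
  st <- orica_init(7)
  res <- orica_process(st, rec)
  res <- orica_process(res$state, rec)
  fl <- flag_artifact_components(res$activations, rec, corr_threshold = 0.3)
  expect_gt(length(fl), 0)
  clean <- reconstruct_clean(rec, res$state, fl)
  eog <- rec$data[eog_channels(rec), ]
  eog_var <- function(r) {
    sum(vapply(eeg_channels(rec), function(ch) {
      fit <- stats::lm(r$data[ch, ] ~ eog)
      summary(fit)$r.squared * stats::var(r$data[ch, ])
    }, numeric(1)))
  }
  expect_lt(eog_var(clean), 0.5 * eog_var(rec))
})
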