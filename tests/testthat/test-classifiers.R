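two_blobs <- function(seed = 1, n = 20, sep = 4, sd = 0.5) {
  gaussian_blobs(n, rbind(c(-sep / 2, 0), c(sep / 2, 0)), sd = sd, seed = seed)
}

test_that("a separable two-class problem is learned perfectly", {
  for (seed in c(51, 52, 53)) {
    b <- two_blobs(seed = seed, n = 20)
    m <- train_svm(b$x, b$y, kernel = "linear", seed = 1)
    pr <- predict(m, b$x)
    expect_equal(pr$label, b$y)
    ## far point: confident posterior
    far <- predict(m, c(-4, 0))
    expect_equal(far$label, 1L)
    expect_gt(far$posterior[1, "1"], 0.9)
  }
})

test_that("class renaming permutes predictions identically", {
  b <- gaussian_blobs(12, rbind(c(0, 3), c(3, 0), c(-3, 0)), sd = 0.6,
                      seed = 52)
  m1 <- train_svm(b$x, b$y, seed = 3)
  remap <- c(3L, 1L, 2L)
  m2 <- train_svm(b$x, remap[b$y], seed = 3)
  set.seed(53)
  probe <- matrix(rnorm(40), 20)
  p1 <- predict(m1, probe)$label
  p2 <- predict(m2, probe)$label
  expect_equal(p2, remap[p1])
})

test_that("training-input validation", {
  b <- two_blobs(seed = 54)
  expect_error(train_svm(b$x, rep(1, nrow(b$x))), ">= 2 classes")
  expect_error(train_svm(b$x, c(1, rep(2, nrow(b$x) - 1))), ">= 2 samples")
  xb <- b$x; xb[1, 1] <- NA
  expect_error(train_svm(xb, b$y), "non-finite")
  m <- train_svm(b$x, b$y)
  expect_error(predict(m, c(1, 2, 3)), "dimension")
})

test_that("Platt calibration matches an independent likelihood fit", {
  set.seed(55)
  dec <- c(rnorm(30, 1.2, 0.8), rnorm(30, -0.8, 0.8))
  pos <- rep(c(TRUE, FALSE), each = 30)
  fit <- bcidecode:::platt_fit(dec, pos)
  ## independent oracle: same smoothed-target likelihood minimized by a
  ## coarse grid followed by general-purpose optimization
  n1 <- sum(pos); n0 <- sum(!pos)
  t <- ifelse(pos, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(ab) {
    f <- ab[1] * dec + ab[2]
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  grid <- expand.grid(A = seq(-6, 0, by = 0.25), B = seq(-3, 3, by = 0.25))
  best <- grid[which.min(apply(grid, 1, nll)), ]
  oracle <- optim(as.numeric(best), nll, method = "BFGS")
  expect_lte(fit$nll, oracle$value + 1e-4)
  expect_equal(fit$nll, oracle$value, tolerance = 1e-4)
  ## the sigmoid is monotone in the decision value
  p <- bcidecode:::platt_prob(seq(-3, 3, by = 0.1), fit)
  expect_true(all(diff(p) > 0) || all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("coupled posteriors normalize and drive the label", {
  b <- gaussian_blobs(10, rbind(c(0, 2.5), c(2.5, 0), c(-2.5, 0)), sd = 0.7,
                      seed = 56)
  m <- train_svm(b$x, b$y, seed = 1)
  set.seed(57)
  probe <- matrix(rnorm(60, sd = 2), 30)
  pr <- predict(m, probe)
  expect_equal(rowSums(pr$posterior), rep(1, 30), tolerance = 1e-9)
  expect_equal(pr$label,
               as.integer(colnames(pr$posterior)[max.col(pr$posterior,
                                                         "first")]))
  ## two-class: label flips exactly where the posterior crosses 0.5
  b2 <- two_blobs(seed = 58)
  m2 <- train_svm(b2$x, b2$y, seed = 1)
  line <- cbind(seq(-3, 3, length.out = 101), 0)
  pr2 <- predict(m2, line)
  expect_equal(pr2$label == 1L, pr2$posterior[, "1"] > 0.5)
})

test_that("the confidence gate at th = 1 reproduces the static model", {
  b <- two_blobs(seed = 59, sd = 1.2)
  m <- train_svm(b$x, b$y, seed = 2)
  set.seed(60)
  stream <- matrix(rnorm(60, sd = 2), 30)
  st <- adaptive_state(m, th = 1, cap = 100)
  ra <- run_adaptive(m, stream, st)
  expect_identical(ra$predictions, predict(m, stream)$label)
  expect_equal(ra$state$accepted, 0L)
  expect_equal(ra$state$rejected, 30L)
})

test_that("th = 0 accepts a single sample and refits once", {
  b <- two_blobs(seed = 61)
  m <- train_svm(b$x, b$y, seed = 2)
  st <- adaptive_state(m, th = 0, cap = 100)
  n0 <- nrow(st$Tx)
  out <- adapt_step(m, st, c(0.5, 0.5))
  expect_true(out$updated)
  expect_equal(nrow(out$state$Tx), n0 + 1L)
  expect_equal(out$state$accepted, 1L)
  expect_equal(out$state$updates, 1L)
})

test_that("the working set never exceeds its cap", {
  b <- two_blobs(seed = 62, n = 30)
  m <- train_svm(b$x, b$y, seed = 2)
  st <- adaptive_state(m, th = 0, cap = 40)
  set.seed(63)
  stream <- matrix(rnorm(200, sd = 2), 100)
  ra <- run_adaptive(m, stream, st)
  expect_lte(nrow(ra$state$Tx), 40)
  expect_equal(ra$state$accepted, 100L)
  ## initial support vectors are never evicted
  expect_equal(ra$state$Tx[seq_len(ra$state$n_init), ],
               st$Tx[seq_len(st$n_init), ])
})

test_that("streaming equals manually folded adapt_step", {
  b <- two_blobs(seed = 64)
  m <- train_svm(b$x, b$y, seed = 2)
  set.seed(65)
  stream <- matrix(rnorm(20, sd = 2), 10)
  st <- adaptive_state(m, th = 0.7, cap = 60)
  ra <- run_adaptive(m, stream, st)
  m2 <- m; st2 <- adaptive_state(m, th = 0.7, cap = 60)
  manual <- integer(10)
  for (i in 1:10) {
    out <- adapt_step(m2, st2, stream[i, ])
    m2 <- out$model; st2 <- out$state
    manual[i] <- out$label
  }
  expect_identical(ra$predictions, manual)
  ## empty stream
  ra0 <- run_adaptive(m, matrix(numeric(0), 0, 2))
  expect_length(ra0$predictions, 0)
  expect_equal(ra0$state$accepted + ra0$state$rejected, 0L)
})

test_that("adaptation tracks a drifting class distribution", {
  ## 2-class stream whose means rotate slowly; true labels are withheld
  ## from adaptation and only used for scoring
  wins <- 0; diffs <- numeric(20)
  for (seed in 1:20) {
    set.seed(700 + seed)
    train <- two_blobs(seed = 700 + seed, n = 25, sep = 3, sd = 0.7)
    m <- train_svm(train$x, train$y, seed = seed)
    n_s <- 120
    angle <- seq(0, pi / 2, length.out = n_s)
    y <- sample(1:2, n_s, replace = TRUE)
    mu <- function(k, a) 1.5 * c(cos(a + (k == 1) * pi), sin(a + (k == 1) * pi))
    stream <- t(vapply(seq_len(n_s), function(i)
      mu(y[i], angle[i]) + rnorm(2, sd = 0.7), numeric(2)))
    static_acc <- mean(predict(m, stream)$label == y)
    ra <- run_adaptive(m, stream, adaptive_state(m, th = 0.7, cap = 200))
    adap_acc <- mean(ra$predictions == y)
    diffs[seed] <- adap_acc - static_acc
    if (adap_acc >= static_acc) wins <- wins + 1
  }
  expect_gt(mean(diffs), 0)
})

test_that("LDA matches closed forms and the reference implementation", {
  b <- two_blobs(seed = 66, n = 40, sep = 3, sd = 1)
  m <- train_lda(b$x, b$y)
  ## the midpoint of the class means lies exactly on the boundary (equal
  ## priors); symmetric probes along the mean difference flip the label
  mid <- colMeans(m$means)
  d <- m$means[2, ] - m$means[1, ]
  pr <- predict(m, rbind(mid, mid + d * 0.2, mid - d * 0.2))
  expect_equal(unname(pr$posterior[1, 1]), 0.5, tolerance = 1e-9)
  expect_equal(pr$label[2:3], c(2L, 1L))
  ## closed-form oracle computed from scratch in the test
  X1 <- b$x[b$y == 1, ]; X2 <- b$x[b$y == 2, ]
  Sp <- (crossprod(scale(X1, scale = FALSE)) +
         crossprod(scale(X2, scale = FALSE))) / (nrow(b$x) - 2)
  w_oracle <- solve(Sp, colMeans(X2) - colMeans(X1))
  w_got <- m$Sigma_inv %*% (m$means[2, ] - m$means[1, ])
  expect_equal(as.numeric(w_got), as.numeric(w_oracle), tolerance = 1e-8)
  ## posteriors agree with MASS::lda as an independent implementation
  ref <- MASS::lda(b$x, grouping = b$y)
  set.seed(67)
  probes <- matrix(rnorm(40, sd = 2), 20)
  p_ref <- predict(ref, probes)$posterior
  p_got <- predict(m, probes)$posterior
  expect_equal(unname(p_got), unname(p_ref), tolerance = 1e-6)
})

test_that("identical class distributions give indifferent posteriors", {
  set.seed(68)
  X <- matrix(rnorm(80), 40)
  Xdup <- rbind(X, X)
  y <- rep(1:2, each = 40)
  m <- train_lda(Xdup, y)
  pr <- predict(m, matrix(rnorm(10), 5))
  expect_equal(pr$posterior, matrix(0.5, 5, 2), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("singular pooled covariance asks for shrinkage", {
  X <- cbind(1:20, (1:20) * 2)  # collinear features
  y <- rep(1:2, 10)
  expect_error(train_lda(X, y), "shrinkage")
  expect_s3_class(train_lda(X, y, shrinkage = 0.1), "bci_lda")
})

test_that("global-mean adaptation shifts means and nothing else", {
  b <- two_blobs(seed = 69)
  m <- train_lda(b$x, b$y)
  expect_equal(adapt_lda_global_mean(m, c(5, 5), eta = 0), m)
  m1 <- adapt_lda_global_mean(m, c(5, 5), eta = 1)
  expect_equal(m1$mu_g, c(5, 5))
  expect_equal(m1$Sigma, m$Sigma)
  expect_equal(m1$means - m$means,
               matrix(rep(c(5, 5) - m$mu_g, each = 2), 2),
               tolerance = 1e-12)
})

test_that("global-mean LDA adaptation tracks a translation drift", {
  diffs <- numeric(20)
  for (seed in 1:20) {
    train <- two_blobs(seed = 800 + seed, n = 25, sep = 3, sd = 0.8)
    m <- train_lda(train$x, train$y)
    set.seed(800 + seed)
    n_s <- 120
    y <- sample(1:2, n_s, replace = TRUE)
    shift <- cbind(seq(0, 3, length.out = n_s), seq(0, 2, length.out = n_s))
    centers <- rbind(c(-1.5, 0), c(1.5, 0))
    stream <- centers[y, ] + shift + matrix(rnorm(2 * n_s, sd = 0.8), n_s)
    static_acc <- mean(predict(m, stream)$label == y)
    adap_acc <- mean(run_adaptive_lda(m, stream, eta = 0.1)$predictions == y)
    diffs[seed] <- adap_acc - static_acc
  }
  expect_gt(mean(diffs), 0)
})

test_that("posterior probabilities are coarsely calibrated", {
  ## overlapping Gaussians: reliability curve slope in [0.7, 1.3]
  train <- two_blobs(seed = 70, n = 100, sep = 2, sd = 1)
  m <- train_svm(train$x, train$y, seed = 5)
  test <- two_blobs(seed = 71, n = 1000, sep = 2, sd = 1)
  pr <- predict(m, test$x)
  p1 <- pr$posterior[, "1"]
  correct1 <- as.numeric(test$y == 1)
  bins <- cut(p1, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  emp <- tapply(correct1, bins, mean)
  pred <- tapply(p1, bins, mean)
  n_bin <- tapply(p1, bins, length)
  ok <- !is.na(emp) & n_bin >= 30
  slope <- stats::coef(stats::lm(emp[ok] ~ pred[ok],
                                 weights = n_bin[ok]))[2]
  expect_gt(slope, 0.7)
  expect_lt(slope, 1.3)
})
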