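#' Train a regularized LDA classifier
#'
#' Standard Gaussian linear discriminant analysis: per-class means, pooled
#' within-class covariance (optionally shrunk towards a scaled identity),
#' and empirical priors. The global feature mean is stored for
#' class-unspecific adaptation via [adapt_lda_global_mean()].
#'
#' @param features trials x features matrix.
#' @param labels integer class labels.
#' @param shrinkage shrinkage weight in `[0, 1]` towards
#'   `mean(diag(Sigma)) * I`.
#' @return a `bci_lda` model.
#' @export
train_lda <- function(features, labels, shrinkage = 0) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  assert_scalar_num(shrinkage, "shrinkage", lo = 0, hi = 1)
  if (nrow(features) != length(labels))
    stop_config("features and labels lengths differ")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_config("need >= 2 classes")
  d <- ncol(features)
  n <- nrow(features)
  means <- t(vapply(classes, function(k)
    colMeans(features[labels == k, , drop = FALSE]), numeric(d)))
  Sw <- matrix(0, d, d)
  for (ki in seq_along(classes)) {
    Xc <- sweep(features[labels == classes[ki], , drop = FALSE], 2, means[ki, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sigma <- Sw / (n - length(classes))
  if (shrinkage > 0)
    Sigma <- (1 - shrinkage) * Sigma +
      shrinkage * mean(diag(Sigma)) * diag(d)
  Sigma_inv <- tryCatch(solve(Sigma), error = function(e)
    stop_config("pooled covariance is singular; increase `shrinkage`"))
  priors <- as.numeric(table(factor(labels, classes)) / n)
  structure(list(classes = classes, means = means, Sigma = Sigma,
                 Sigma_inv = Sigma_inv, priors = priors,
                 mu_g = colMeans(features), shrinkage = shrinkage),
            class = "bci_lda")
}

#' @export
print.bci_lda <- function(x, ...) {
  cat(sprintf("<bci_lda> %d classes, %d features, shrinkage %g\n",
              length(x$classes), ncol(x$means), x$shrinkage))
  invisible(x)
}

#' Predict with an LDA model
#'
#' @param object a `bci_lda`.
#' @param newdata feature vector or matrix.
#' @param ... unused.
#' @return list with `label` and softmax `posterior` matrix.
#' @export
predict.bci_lda <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  K <- length(object$classes)
  disc <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    mu <- object$means[k, ]
    w <- object$Sigma_inv %*% mu
    disc[, k] <- X %*% w - 0.5 * sum(mu * w) + log(object$priors[k])
  }
  post <- exp(disc - apply(disc, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  list(label = as.integer(object$classes[max.col(post, ties.method = "first")]),
       posterior = post)
}

#' Unsupervised global-mean adaptation of LDA
#'
#' Class-unspecific adaptation: the global mean is moved towards the new
#' sample, `mu_g <- (1 - eta) mu_g + eta x`, and every class mean is
#' shifted by the same displacement. The covariance is untouched and the
#' sample's label is never used, so the rule is safe under free BCI use.
#'
#' @param model a `bci_lda`.
#' @param x one feature vector.
#' @param eta adaptation rate in `[0, 1]`.
#' @return the adapted `bci_lda`.
#' @export
adapt_lda_global_mean <- function(model, x, eta = 0.05) {
  stopifnot(inherits(model, "bci_lda"))
  assert_scalar_num(eta, "eta", lo = 0, hi = 1)
  mu_new <- (1 - eta) * model$mu_g + eta * as.numeric(x)
  shift <- mu_new - model$mu_g
  model$means <- sweep(model$means, 2, shift, `+`)
  model$mu_g <- mu_new
  model
}

#' Run the adaptive LDA over a sample stream
#'
#' Predicts each sample with the current model, then applies the
#' global-mean update; labels are never consulted.
#'
#' @param model a `bci_lda`.
#' @param stream samples x features matrix.
#' @param eta adaptation rate per sample.
#' @return list with `predictions`, `posteriors` (winning probability),
#'   and the final `model`.
#' @export
run_adaptive_lda <- function(model, stream, eta = 0.05) {
  stream <- as.matrix(stream)
  n <- nrow(stream)
  preds <- integer(n); post <- numeric(n)
  for (i in seq_len(n)) {
    pr <- predict(model, stream[i, ])
    preds[i] <- pr$label[1]
    post[i] <- max(pr$posterior[1, ])
    model <- adapt_lda_global_mean(model, stream[i, ], eta)
  }
  list(predictions = preds, posteriors = post, model = model)
}
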