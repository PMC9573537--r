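## Platt sigmoid fit: maps decision values to P(positive | f) =
## 1 / (1 + exp(A f + B)) by penalized maximum likelihood with the
## standard smoothed targets; Newton iteration with backtracking.
platt_fit <- function(dec, pos, max_iter = 100, min_step = 1e-10,
                      sigma = 1e-12) {
  pos <- as.logical(pos)
  n1 <- sum(pos); n0 <- sum(!pos)
  t <- ifelse(pos, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  fval <- function(A, B) {
    f <- A * dec + B
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    f <- A * dec + B
    p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sum(dec^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    d1 <- t - p
    g1 <- sum(dec * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      if (step < min_step) return(list(A = A, B = B, nll = fv))
      nA <- A + step * dA; nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) {
        A <- nA; B <- nB; fv <- nf
        break
      }
      step <- step / 2
    }
  }
  list(A = A, B = B, nll = fv)
}

platt_prob <- function(dec, AB) {
  f <- AB$A * dec + AB$B
  ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
}

## fit one binary libsvm machine; `flip` makes positive decision values
## point at the first class of the pair regardless of libsvm's internal
## label ordering
fit_pair_svm <- function(x, y, pair, kernel, C, gamma, coef0) {
  fit <- e1071::svm(x = x, y = factor(y, levels = pair),
                    kernel = kernel, cost = C, gamma = gamma, coef0 = coef0,
                    scale = TRUE, probability = FALSE)
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  flip <- if (mean(dv[y == pair[1]]) >= mean(dv[y == pair[2]])) 1 else -1
  list(fit = fit, flip = flip)
}

pair_decision <- function(machine, x) {
  dv <- attr(predict(machine$fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  machine$flip * dv
}

#' Train a multiclass kernel SVM with Platt posteriors
#'
#' One-vs-one decomposition: one kernel SVM per class pair plus a Platt
#' sigmoid per pair mapping decision values to pairwise posterior
#' probabilities. Calibration is fitted on cross-validated decision values
#' (fold assignment stratified by class and seeded) rather than training
#' decision values, which are optimistically biased. The default kernel is
#' the sigmoid `tanh(gamma * <x, x'> + coef0)` with unit scale and zero
#' offset.
#'
#' @param features numeric matrix, trials x features.
#' @param labels integer class labels, >= 2 classes, >= 2 samples each.
#' @param kernel `"sigmoid"`, `"radial"`, or `"linear"`.
#' @param C regularization cost.
#' @param gamma kernel scale; `NULL` uses the libsvm convention
#'   `1/n_features`. Features are standardized inside each machine, which
#'   keeps `gamma * <x, x'>` in tanh's responsive range (a unit-scale
#'   sigmoid kernel on raw log-variance features saturates).
#' @param coef0 kernel offset (sigmoid/polynomial).
#' @param cv_folds folds for Platt calibration (>= 2); fold assignment is
#'   deterministic (positional within class) so results are reproducible
#'   and invariant under class renaming.
#' @param seed retained for interface stability; fitting is deterministic.
#' @return a `bci_svm` model.
#' @export
train_svm <- function(features, labels, kernel = c("sigmoid", "radial", "linear"),
                      C = 1, gamma = NULL, coef0 = 0, cv_folds = 3, seed = 1) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  gamma <- gamma %||% (1 / ncol(features))
  if (any(!is.finite(features))) stop_config("non-finite feature values")
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop_config("features and labels lengths differ")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_config("need >= 2 classes to train an SVM")
  if (any(tabulate(factor(labels, classes)) < 2))
    stop_config("every class needs >= 2 samples")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- vector("list", length(pairs))
  platt <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    idx <- which(labels %in% pr)
    xi <- features[idx, , drop = FALSE]
    yi <- labels[idx]
    machines[[pi]] <- fit_pair_svm(xi, yi, pr, kernel, C, gamma, coef0)
    ## stratified CV decision values for calibration; folds are assigned
    ## positionally within each class so calibration (and therefore
    ## prediction) is invariant under class renaming
    folds <- integer(length(yi))
    for (cl in pr) {
      ci <- which(yi == cl)
      folds[ci] <- rep_len(seq_len(cv_folds), length(ci))
    }
    dec_cv <- numeric(length(yi))
    ok <- TRUE
    for (fo in seq_len(cv_folds)) {
      tr <- folds != fo
      if (length(unique(yi[tr])) < 2 || sum(tr) < 2) { ok <- FALSE; break }
      mfo <- fit_pair_svm(xi[tr, , drop = FALSE], yi[tr], pr, kernel, C,
                          gamma, coef0)
      dec_cv[!tr] <- pair_decision(mfo, xi[!tr, , drop = FALSE])
    }
    if (!ok) dec_cv <- pair_decision(machines[[pi]], xi)
    platt[[pi]] <- platt_fit(dec_cv, yi == pr[1])
  }
  structure(list(classes = classes, pairs = pairs, machines = machines,
                 platt = platt, kernel = kernel, C = C, gamma = gamma,
                 coef0 = coef0, cv_folds = cv_folds, seed = seed,
                 X_train = features, y_train = labels),
            class = "bci_svm")
}

#' @export
print.bci_svm <- function(x, ...) {
  cat(sprintf("<bci_svm> %d classes, %d pairwise %s-kernel machines, C = %g\n",
              length(x$classes), length(x$pairs), x$kernel, x$C))
  invisible(x)
}

## Wu-Lin pairwise coupling (their second method): given pairwise
## posteriors r[i,j] = P(i | {i,j}), solve the constrained least-squares
## system for class posteriors p with sum(p) = 1
couple_posteriors <- function(R) {
  K <- nrow(R)
  if (K == 2) {
    p <- c(R[1, 2], R[2, 1])
    return(p / sum(p))
  }
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i == j) {
        Q[i, i] <- sum(R[-i, i]^2)
      } else {
        Q[i, j] <- -R[j, i] * R[i, j]
      }
    }
  }
  M <- rbind(cbind(Q, 1), c(rep(1, K), 0))
  sol <- tryCatch(solve(M, c(rep(0, K), 1)), error = function(e) NULL)
  p <- if (is.null(sol)) rep(1 / K, K) else sol[seq_len(K)]
  p <- pmax(p, 0)
  if (sum(p) <= 0) p <- rep(1 / K, K)
  p / sum(p)
}

svm_posterior_one <- function(model, x) {
  K <- length(model$classes)
  R <- matrix(0.5, K, K)
  xm <- matrix(x, nrow = 1)
  for (pi in seq_along(model$pairs)) {
    pr <- model$pairs[[pi]]
    i <- match(pr[1], model$classes); j <- match(pr[2], model$classes)
    d <- pair_decision(model$machines[[pi]], xm)
    rij <- platt_prob(d, model$platt[[pi]])
    rij <- min(max(rij, 1e-10), 1 - 1e-10)
    R[i, j] <- rij
    R[j, i] <- 1 - rij
  }
  couple_posteriors(R)
}

#' Predict class labels and coupled posteriors
#'
#' @param object a `bci_svm`.
#' @param newdata feature vector or trials x features matrix.
#' @param ... unused.
#' @return list with `label` (integer vector) and `posterior` (matrix,
#'   rows summing to 1, columns named by class).
#' @export
predict.bci_svm <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(X) != ncol(object$X_train))
    stop_config("feature dimension ", ncol(X), " does not match model (",
                ncol(object$X_train), ")")
  post <- t(apply(X, 1, function(x) svm_posterior_one(object, x)))
  colnames(post) <- object$classes
  label <- object$classes[max.col(post, ties.method = "first")]
  list(label = as.integer(label), posterior = post)
}

#' Initialize the confidence-gated adaptation state
#'
#' The working set `T` starts from the samples that are support vectors of
#' any pairwise machine (with their true training labels); streamed
#' samples whose predicted posterior clears the threshold join it with
#' their *predicted* label, FIFO-capped so memory stays bounded.
#'
#' @param model a trained `bci_svm`.
#' @param th posterior acceptance threshold in (0, 1].
#' @param cap maximum working-set size.
#' @return an `adaptive_state`.
#' @export
adaptive_state <- function(model, th = 0.7, cap = 500) {
  stopifnot(inherits(model, "bci_svm"))
  assert_scalar_num(th, "th", lo = 0, hi = 1)
  cap <- assert_count(cap, "cap")
  sv <- sort(unique(unlist(lapply(seq_along(model$pairs), function(pi) {
    idx_pair <- which(model$y_train %in% model$pairs[[pi]])
    idx_pair[model$machines[[pi]]$fit$index]
  }))))
  if (cap < length(sv))
    stop_config("cap (", cap, ") smaller than the initial support set (",
                length(sv), ")")
  structure(list(th = th, cap = cap,
                 Tx = model$X_train[sv, , drop = FALSE],
                 Ty = model$y_train[sv],
                 n_init = length(sv),
                 accepted = 0L, rejected = 0L, updates = 0L),
            class = "adaptive_state")
}

refit_on_working_set <- function(model, state) {
  for (pi in seq_along(model$pairs)) {
    pr <- model$pairs[[pi]]
    idx <- which(state$Ty %in% pr)
    if (length(idx) < 2 || length(unique(state$Ty[idx])) < 2) next
    model$machines[[pi]] <- fit_pair_svm(state$Tx[idx, , drop = FALSE],
                                         state$Ty[idx], pr, model$kernel,
                                         model$C, model$gamma, model$coef0)
  }
  model
}

#' One step of confidence-gated adaptation
#'
#' Predicts the sample; if the winning coupled posterior exceeds `th`, the
#' sample enters the working set under its predicted label (evicting the
#' oldest non-initial member when at capacity) and every pairwise machine
#' is refit on the working set. Platt calibration parameters stay fixed at
#' their initial fit. With `th = 1` no sample is ever accepted and the
#' model never changes.
#'
#' @param model a `bci_svm`.
#' @param state an `adaptive_state`.
#' @param x one feature vector.
#' @return list `label`, `posterior` (winning probability), `updated`
#'   (flag), `model`, `state`.
#' @export
adapt_step <- function(model, state, x) {
  stopifnot(inherits(model, "bci_svm"), inherits(state, "adaptive_state"))
  pr <- predict(model, x)
  v <- max(pr$posterior[1, ])
  u <- pr$label[1]
  updated <- FALSE
  if (v > state$th) {
    state$Tx <- rbind(state$Tx, matrix(x, nrow = 1))
    state$Ty <- c(state$Ty, u)
    if (nrow(state$Tx) > state$cap) {
      drop <- state$n_init + 1L
      state$Tx <- state$Tx[-drop, , drop = FALSE]
      state$Ty <- state$Ty[-drop]
    }
    model <- refit_on_working_set(model, state)
    state$accepted <- state$accepted + 1L
    state$updates <- state$updates + 1L
    updated <- TRUE
  } else {
    state$rejected <- state$rejected + 1L
  }
  list(label = u, posterior = v, updated = updated, model = model,
       state = state)
}

#' Run the adaptive SVM over a sample stream
#'
#' Applies [adapt_step()] to each row of the stream in order; true labels
#' are never consulted.
#'
#' @param model a `bci_svm`.
#' @param stream samples x features matrix (processed row by row).
#' @param state an `adaptive_state` (default: fresh state at `th = 0.7`).
#' @return list with `predictions`, `posteriors`, per-sample `log`
#'   data.frame (`index`, `label`, `posterior`, `accepted`), final `model`
#'   and `state`.
#' @export
run_adaptive <- function(model, stream, state = adaptive_state(model)) {
  stream <- as.matrix(stream)
  n <- nrow(stream)
  preds <- integer(n); post <- numeric(n); acc <- logical(n)
  for (i in seq_len(n)) {
    st <- adapt_step(model, state, stream[i, ])
    model <- st$model; state <- st$state
    preds[i] <- st$label; post[i] <- st$posterior; acc[i] <- st$updated
  }
  list(predictions = preds, posteriors = post,
       log = data.frame(index = seq_len(n), label = preds,
                        posterior = post, accepted = acc),
       model = model, state = state)
}
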