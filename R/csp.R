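#' Per-class normalized spatial covariances
#'
#' Concatenates every trial of a class along time into one channels x
#' samples block `U_k` and returns `S_k = U_k U_k' / trace(U_k U_k')`, so
#' each class covariance has unit trace. Rank-deficient covariances are
#' shrunk towards the trace-normalized identity with a warning.
#'
#' @param trials a `trial_tensor` from [epoch()].
#' @param rho shrinkage weight towards `I / n_channels` (numerical guard).
#' @return named list, one unit-trace covariance per class label present.
#' @export
class_covariances <- function(trials, rho = 1e-6) {
  stopifnot(inherits(trials, "trial_tensor"))
  labels <- trials$labels
  if (length(labels) == 0) stop_config("no trials")
  n_ch <- dim(trials$trials)[2]
  out <- list()
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    if (length(idx) < 2)
      stop_config("class ", k, " has fewer than 2 trials")
    U <- do.call(cbind, lapply(idx, function(i)
      matrix(trials$trials[i, , ], n_ch)))
    S <- tcrossprod(U)
    tr <- sum(diag(S))
    if (tr <= 0) stop_config("class ", k, " has all-zero trials")
    S <- S / tr
    r <- rho
    if (qr(S)$rank < n_ch) {
      warning("rank-deficient class covariance for class ", k,
              "; raising regularization")
      r <- max(rho, 1e-4)
    }
    S <- (1 - r) * S + r * diag(n_ch) / n_ch
    out[[as.character(k)]] <- S / sum(diag(S))
  }
  out
}

## eigendecomposition with deterministic sign (largest-|coef| positive) and
## tie-break (descending eigenvalue, then ascending original index)
eigen_sorted <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ord <- order(-e$values, seq_along(e$values))
  vec <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  list(values = e$values[ord], vectors = vec)
}

#' Fit a one-vs-rest multiclass CSP model
#'
#' Whitens the composite covariance `Sc = sum_k S_k` through
#' `M = D^{-1/2} Uo'` (so `M Sc M' = I`), then for each class
#' eigendecomposes the whitened class covariance `W_k = M S_k M'`. Because
#' the rest-of-classes covariance satisfies `W_k + W_k' = I` after
#' composite whitening, eigenvectors with the largest eigenvalues of `W_k`
#' maximize class-k variance against the pooled rest. The `m` leading
#' filters per class, `P_k = U_k' M`, are stacked class by class into the
#' projection bank `Ps`.
#'
#' @param trials a labeled `trial_tensor` with >= 2 classes.
#' @param m filters kept per class (1..n_channels).
#' @param rho covariance shrinkage passed to [class_covariances()].
#' @return a `csp_model`: `M`, per-class `Wk`, eigenvalues, full and
#'   selected projections, bank `Ps`, `m`, `classes`.
#' @export
fit_csp <- function(trials, m = 2, rho = 1e-6) {
  stopifnot(inherits(trials, "trial_tensor"))
  S <- class_covariances(trials, rho = rho)
  classes <- as.integer(names(S))
  if (length(classes) < 2) stop_config("need >= 2 classes to fit CSP")
  n_ch <- nrow(S[[1]])
  m <- assert_count(m, "m")
  if (m > n_ch) stop_config("m (", m, ") may not exceed the channel count (",
                            n_ch, ")")
  Sc <- Reduce(`+`, S)
  if (any(!is.finite(Sc))) stop_config("non-finite composite covariance")
  eo <- eigen_sorted(Sc)
  if (min(eo$values) <= 0)
    stop_config("composite covariance not positive definite")
  M <- diag(1 / sqrt(eo$values)) %*% t(eo$vectors)
  Wk <- lapply(S, function(Sk) M %*% Sk %*% t(M))
  decomp <- lapply(Wk, eigen_sorted)
  P_full <- lapply(decomp, function(d) t(d$vectors) %*% M)
  eigvals <- lapply(decomp, function(d) d$values)
  sel <- lapply(seq_along(classes), function(j) seq_len(m))
  Ps <- do.call(rbind, lapply(seq_along(classes), function(j)
    P_full[[j]][sel[[j]], , drop = FALSE]))
  structure(list(M = M, S = S, Wk = Wk, eigenvalues = eigvals,
                 P_full = P_full, selected = sel, Ps = Ps, m = m,
                 classes = classes, n_channels = n_ch),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d classes x %d filters on %d channels (%d features)\n",
              length(x$classes), x$m, x$n_channels, nrow(x$Ps)))
  invisible(x)
}

#' Project a trial through the CSP bank
#'
#' @param model a `csp_model`.
#' @param trial channels x samples matrix.
#' @return (n_classes * m) x samples matrix `Ps %*% trial`.
#' @export
apply_csp <- function(model, trial) {
  stopifnot(inherits(model, "csp_model"))
  if (!is.matrix(trial)) trial <- matrix(trial, nrow = model$n_channels)
  if (nrow(trial) != model$n_channels)
    stop_config("trial has ", nrow(trial), " channels, model expects ",
                model$n_channels)
  model$Ps %*% trial
}

#' Log-normalized-variance features
#'
#' For each projected row, `V_m` is its variance over samples and the
#' feature is `fv_m = log(V_m / sum(V))`; by construction
#' `sum(exp(fv)) = 1`.
#'
#' @param projected filters x samples matrix from [apply_csp()].
#' @return list with `fv` (log-normalized variances) and `V` (raw
#'   variances).
#' @export
log_variance_features <- function(projected) {
  if (!is.matrix(projected)) projected <- matrix(projected, nrow = 1)
  if (ncol(projected) < 2) stop_config("need >= 2 samples per row")
  V <- apply(projected, 1, var)
  tot <- sum(V)
  if (tot <= 0) stop_config("all-zero projection: variance sum is zero")
  list(fv = log(V / tot), V = V)
}

#' Feature matrix for a trial tensor
#'
#' Convenience wrapper: projects every trial and stacks the log-variance
#' features into a trials x features matrix.
#'
#' @param model a `csp_model`.
#' @param trials a `trial_tensor`.
#' @return list with `features` (matrix) and `labels`.
#' @export
csp_features <- function(model, trials) {
  stopifnot(inherits(trials, "trial_tensor"))
  n <- dim(trials$trials)[1]
  feats <- t(vapply(seq_len(n), function(i)
    log_variance_features(apply_csp(model,
      matrix(trials$trials[i, , ], model$n_channels)))$fv,
    numeric(nrow(model$Ps))))
  list(features = feats, labels = trials$labels)
}

#' Re-rank CSP filters by class-discriminative power
#'
#' Scores every candidate filter of each class bank by the Fisher ratio of
#' its per-trial log-variance across classes (between-class variance of
#' class means over mean within-class variance) and keeps the `m`
#' top-scoring filters per class. A filter whose log-variance does not
#' differ across classes scores 0 and is ranked last. Deterministic; ties
#' break by original eigenvalue order.
#'
#' @param model a fitted `csp_model`.
#' @param trials labeled training `trial_tensor`.
#' @return a `csp_model` with re-selected filters and rebuilt `Ps`.
#' @export
refine_filters <- function(model, trials) {
  stopifnot(inherits(model, "csp_model"), inherits(trials, "trial_tensor"))
  n <- dim(trials$trials)[1]
  labels <- trials$labels
  for (j in seq_along(model$classes)) {
    Pk <- model$P_full[[j]]
    lv <- matrix(0, n, nrow(Pk))
    for (i in seq_len(n)) {
      proj <- Pk %*% matrix(trials$trials[i, , ], model$n_channels)
      v <- apply(proj, 1, var)
      lv[i, ] <- log(pmax(v, 1e-300))
    }
    score <- vapply(seq_len(ncol(lv)), function(f) {
      mu_k <- tapply(lv[, f], labels, mean)
      s2_k <- tapply(lv[, f], labels, var)
      between <- var(as.numeric(mu_k))
      within <- mean(s2_k, na.rm = TRUE)
      if (!is.finite(between) || between <= 0) return(0)
      between / max(within, 1e-12)
    }, numeric(1))
    ord <- order(-score, seq_along(score))
    model$selected[[j]] <- sort(head(ord, model$m))
  }
  model$Ps <- do.call(rbind, lapply(seq_along(model$classes), function(j)
    model$P_full[[j]][model$selected[[j]], , drop = FALSE]))
  model
}

#' Persist a CSP model as JSON + CSV sidecars
#' @param model a `csp_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_csp_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(model$M, file.path(dir, "M.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$Ps, file.path(dir, "Ps.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(classes = model$classes, m = model$m,
         n_channels = model$n_channels,
         eigenvalues = model$eigenvalues, selected = model$selected),
    file.path(dir, "csp_model.json"), digits = NA)
  invisible(dir)
}
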