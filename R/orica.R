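#' Forgetting-factor schedule for online recursive ICA
#'
#' The per-iteration forgetting factor is
#' `u_i = max(u0 / (i + 1)^decay_gamma, u_min)`: large at the start for
#' fast convergence, annealing towards a floor that keeps slow adaptation
#' alive on nonstationary data.
#'
#' @param u0 initial forgetting factor in (0, 1).
#' @param decay_gamma decay exponent, >= 0.
#' @param u_min floor in `[0, u0)`.
#' @return a `forgetting_schedule` list with an evaluator `u(i)` (0-based
#'   iteration index).
#' @export
forgetting_schedule <- function(u0 = 0.2, decay_gamma = 0.6, u_min = 1e-4) {
  assert_scalar_num(u0, "u0", lo = 1e-12, hi = 1 - 1e-12)
  assert_scalar_num(decay_gamma, "decay_gamma", lo = 0)
  assert_scalar_num(u_min, "u_min", lo = 0)
  if (u_min >= u0) stop_config("u_min must be below u0")
  structure(list(u0 = u0, decay_gamma = decay_gamma, u_min = u_min,
                 u = function(i) pmax(u0 / (i + 1)^decay_gamma, u_min)),
            class = "forgetting_schedule")
}

#' Initialize an ORICA state
#'
#' Whitening matrix `X` and demixing matrix `W` start at the identity; a
#' running channel mean (same forgetting schedule) is maintained for
#' centering during streaming.
#'
#' @param n_channels number of channels (>= 2).
#' @param schedule a [forgetting_schedule()].
#' @param block_size samples per update block (>= 1).
#' @param activation ICA nonlinearity, `"cubic"` (default) or `"tanh"`.
#'   With the recursive rule's rank-one term `a f(a)'`, the cubic
#'   (kurtosis) contrast is the one whose separating fixed point is stable
#'   for super-Gaussian sources; `tanh` is the natural pairing for the
#'   gradient rule's `f(a) a'` orientation.
#' @param rule demixing update: `"recursive"` (forgetting-factor rank-one
#'   rule, the default) or `"gradient"` (plain natural-gradient step with
#'   learning rate `lr`).
#' @param lr learning rate for the gradient rule.
#' @param renormalize if `TRUE`, rows of `W` are rescaled to unit norm
#'   after each block (guards norm inflation on long runs).
#' @return an `orica_state`.
#' @export
orica_init <- function(n_channels, schedule = forgetting_schedule(),
                       block_size = 8, activation = c("cubic", "tanh"),
                       rule = c("recursive", "gradient"), lr = 0.01,
                       renormalize = FALSE) {
  n_channels <- assert_count(n_channels, "n_channels", min = 2L)
  stopifnot(inherits(schedule, "forgetting_schedule"))
  block_size <- assert_count(block_size, "block_size")
  activation <- match.arg(activation)
  rule <- match.arg(rule)
  assert_scalar_num(lr, "lr", lo = 0)
  structure(list(X = diag(n_channels), W = diag(n_channels),
                 mu = numeric(n_channels), i = 0L, last_u = NULL,
                 schedule = schedule, block_size = block_size,
                 activation = activation, rule = rule, lr = lr,
                 renormalize = isTRUE(renormalize)),
            class = "orica_state")
}

#' @export
print.orica_state <- function(x, ...) {
  cat(sprintf("<orica_state> %d channels, %d block iterations, block_size %d, %s/%s rule\n",
              nrow(x$X), x$i, x$block_size, x$activation, x$rule))
  invisible(x)
}

act_fun <- function(state) switch(state$activation, tanh = tanh,
                                  cubic = function(a) a^3)

check_finite_block <- function(xb, state) {
  if (!is.matrix(xb)) xb <- matrix(xb, ncol = 1)
  if (nrow(xb) != nrow(state$X))
    stop_config("block has ", nrow(xb), " channels, state expects ",
                nrow(state$X))
  if (any(!is.finite(xb))) stop_config("non-finite values in input block")
  xb
}

#' One whitening update (block form)
#'
#' Advances the whitening matrix by the recursive rule
#' `X <- X + u/(1-u) * [I - <v v'> / (1 + u(<v'v> - 1))] X`
#' where `v = X x` and `<.>` denotes the block average of the rank-one
#' terms; one forgetting factor per block. The iteration counter advances
#' by one.
#'
#' @param state an `orica_state`.
#' @param x_block channels x samples numeric matrix (already centered).
#' @return the updated `orica_state`.
#' @export
whiten_update <- function(state, x_block) {
  stopifnot(inherits(state, "orica_state"))
  xb <- check_finite_block(x_block, state)
  nb <- ncol(xb)
  u <- state$schedule$u(state$i)
  v <- state$X %*% xb
  Rv <- tcrossprod(v) / nb
  sv <- mean(colSums(v^2))
  denom <- 1 + u * (sv - 1)
  X_new <- state$X + (u / (1 - u)) * (diag(nrow(xb)) - Rv / denom) %*% state$X
  if (any(!is.finite(X_new)))
    stop_config("whitening update diverged at iteration ", state$i)
  state$X <- X_new
  state$i <- state$i + 1L
  state$last_u <- u
  state
}

#' One demixing update (block form)
#'
#' Advances the demixing matrix on a whitened block `v` using either the
#' recursive forgetting-factor rule
#' `W <- W + u/(1-u) * [I - <a f(a)'> / (1 + u(<f(a)'a> - 1))] W`
#' or the gradient rule `W <- W + lr * [I - <f(a) a'>] W`, with
#' `a = W v`. Uses the forgetting factor of the block just consumed by
#' [whiten_update()] so the pair acts as one block iteration.
#'
#' @param state an `orica_state` (normally after [whiten_update()]).
#' @param v_block channels x samples whitened block.
#' @return the updated `orica_state`.
#' @export
demix_update <- function(state, v_block) {
  stopifnot(inherits(state, "orica_state"))
  vb <- check_finite_block(v_block, state)
  nb <- ncol(vb)
  u <- state$last_u %||% state$schedule$u(max(state$i - 1L, 0L))
  a <- state$W %*% vb
  fa <- act_fun(state)(a)
  W_new <- if (state$rule == "recursive") {
    Ra <- a %*% t(fa) / nb
    sf <- mean(colSums(fa * a))
    denom <- 1 + u * (sf - 1)
    state$W + (u / (1 - u)) * (diag(nrow(vb)) - Ra / denom) %*% state$W
  } else {
    state$W + state$lr * (diag(nrow(vb)) - fa %*% t(a) / nb) %*% state$W
  }
  if (any(!is.finite(W_new)))
    stop_config("demixing update diverged at iteration ", state$i)
  if (state$renormalize) {
    rn <- sqrt(rowSums(W_new^2))
    rn[rn == 0] <- 1
    W_new <- W_new / rn
  }
  state$W <- W_new
  state
}

#' Stream a recording through ORICA
#'
#' Cuts the signal into consecutive blocks of `state$block_size` samples
#' (trailing partial block processed as a smaller block) and, per block:
#' updates the running mean, centers, emits activations
#' `a = W X (x - mu)` computed with the block's entry state, then applies
#' the whitening and demixing updates. One block = one forgetting-factor
#' iteration.
#'
#' @param state an `orica_state` from [orica_init()].
#' @param rec an `eeg_recording` (or bare channels x samples matrix).
#' @param center subtract the running mean before whitening (default TRUE).
#' @return list with `activations` (components x samples) and `state`
#'   (the final `orica_state`).
#' @export
orica_process <- function(state, rec, center = TRUE) {
  stopifnot(inherits(state, "orica_state"))
  data <- if (inherits(rec, "eeg_recording")) rec$data else rec
  if (!is.matrix(data)) stop_config("rec must be an eeg_recording or matrix")
  if (nrow(data) != nrow(state$X))
    stop_config("recording has ", nrow(data), " channels, state expects ",
                nrow(state$X))
  if (any(!is.finite(data))) stop_config("non-finite values in recording")
  res <- .orica_stream(data, state$X, state$W, state$mu,
                       as.numeric(state$i), state$schedule$u0,
                       state$schedule$decay_gamma, state$schedule$u_min,
                       state$block_size,
                       ifelse(state$activation == "tanh", 0L, 1L),
                       ifelse(state$rule == "recursive", 0L, 1L),
                       state$lr, state$renormalize, isTRUE(center), TRUE)
  state$X <- res$X
  state$W <- res$W
  state$mu <- as.numeric(res$mu)
  state$i <- as.integer(res$i)
  state$last_u <- state$schedule$u(max(state$i - 1L, 0L))
  list(activations = res$activations, state = state)
}

#' Amari performance index of a separation
#'
#' For `P = T A` (estimated unmixing times true mixing), measures distance
#' from a scaled permutation: 0 means perfect separation, values grow as
#' cross-talk grows. Permutation- and scale-invariant; normalized by
#' `2 n (n - 1)` so a random matrix scores near 1/2.
#'
#' @param T estimated unmixing transform (e.g. `W %*% X`).
#' @param A true mixing matrix.
#' @return scalar index >= 0.
#' @export
amari_index <- function(T, A) {
  P <- T %*% A
  if (nrow(P) != ncol(P)) stop_config("T %*% A must be square")
  P <- abs(P)
  n <- nrow(P)
  row_term <- sum(rowSums(P) / apply(P, 1, max) - 1)
  col_term <- sum(colSums(P) / apply(P, 2, max) - 1)
  (row_term + col_term) / (2 * n * (n - 1))
}

line_power_fraction <- function(x, fs, freq = 50, halfwidth = 1) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  band <- keep & f >= freq - halfwidth & f <= freq + halfwidth
  tot <- sum(p[keep])
  if (tot <= 0) return(0)
  sum(p[band]) / tot
}

#' Flag artifact components
#'
#' Marks components whose absolute correlation with any EOG channel
#' exceeds `corr_threshold` (ocular artifacts) and components whose
#' periodogram concentrates more than `line_frac` of total power within
#' +-1 Hz of `line_freq` (mains contamination). If the recording carries
#' no EOG channel the ocular criterion is skipped with a warning.
#'
#' @param activations components x samples matrix from [orica_process()].
#' @param rec the `eeg_recording` the activations came from.
#' @param corr_threshold absolute-correlation threshold in (0, 1].
#' @param line_freq mains frequency in Hz.
#' @param line_frac power-fraction threshold at the mains frequency.
#' @return sorted integer vector of flagged component indices.
#' @export
flag_artifact_components <- function(activations, rec, corr_threshold = 0.3,
                                     line_freq = 50, line_frac = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(activations) != ncol(rec$data))
    stop_config("activations and recording sample counts differ")
  flagged <- integer(0)
  eog <- eog_channels(rec)
  if (length(eog) == 0) {
    warning("no EOG channels: ocular-correlation criterion skipped")
  } else {
    for (k in seq_len(nrow(activations))) {
      r <- suppressWarnings(
        abs(cor(activations[k, ], t(rec$data[eog, , drop = FALSE]))))
      r[is.na(r)] <- 0
      if (max(r) > corr_threshold) flagged <- c(flagged, k)
    }
  }
  if (line_freq < rec$fs / 2) {
    for (k in seq_len(nrow(activations))) {
      if (line_power_fraction(activations[k, ], rec$fs, line_freq) > line_frac)
        flagged <- c(flagged, k)
    }
  }
  sort(unique(flagged))
}

#' Reconstruct a cleaned recording
#'
#' Back-projects the activations of the final ORICA transform with the
#' rejected components zeroed: `clean = pinv(W X) diag(keep) W X (x - mu)
#' + mu`. With nothing rejected this reproduces the input up to numeric
#' tolerance.
#'
#' @param rec the `eeg_recording` to clean.
#' @param state a converged `orica_state`.
#' @param rejected integer component indices to remove (possibly empty).
#' @return the cleaned `eeg_recording`.
#' @export
reconstruct_clean <- function(rec, state, rejected = integer(0)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(state, "orica_state"))
  n_ch <- nrow(rec$data)
  if (n_ch != nrow(state$X))
    stop_config("recording and state channel counts differ")
  rejected <- as.integer(rejected)
  if (length(rejected) && (min(rejected) < 1 || max(rejected) > n_ch))
    stop_config("rejected component index out of range 1..", n_ch)
  T <- state$W %*% state$X
  act <- T %*% (rec$data - state$mu)
  if (length(rejected)) act[rejected, ] <- 0
  clean <- MASS::ginv(T) %*% act + state$mu
  out <- rec
  out$data <- clean
  out
}
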