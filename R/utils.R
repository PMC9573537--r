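#' @useDynLib bcidecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var cor rnorm runif rpois predict fft
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("bci_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("bci_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a finite numeric scalar")
  if (x < lo || x > hi)
    stop_config(name, " must be in [", lo, ", ", hi, "], got ", x)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_num(x, name, lo = min)
  if (x != as.integer(x)) stop_config(name, " must be an integer count")
  invisible(as.integer(x))
}

#' Evaluate code under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library code does not perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## deterministic child seeds below 2^31, derived from a base seed and a tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}

#' Band power of a signal via the periodogram
#'
#' Mean periodogram power inside `[lo, hi]` Hz, used for line-noise
#' diagnostics and event-related desynchronization checks.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz.
#' @return scalar power (signal units squared).
#' @export
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  if (n < 8) stop_config("band_power needs at least 8 samples")
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  if (!any(keep)) return(0)
  mean(p[keep])
}

round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
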