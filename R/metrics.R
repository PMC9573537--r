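#' Confusion matrix
#'
#' @param y_true,y_pred integer labels in `1..K`, equal length.
#' @param K number of classes.
#' @return K x K count matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(y_true, y_pred, K) {
  K <- assert_count(K, "K", min = 2L)
  if (length(y_true) != length(y_pred))
    stop_config("y_true and y_pred lengths differ")
  if (length(y_true) &&
      (any(y_true < 1 | y_true > K) || any(y_pred < 1 | y_pred > K)))
    stop_config("labels must lie in 1..", K)
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  cm
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed diagonal fraction and `p_e` the product of the row and column
#' marginals. When the marginals force `p_e = 1`, kappa is 1 for perfect
#' agreement and undefined otherwise.
#'
#' @param cm square count matrix from [confusion()].
#' @return scalar kappa, <= 1.
#' @export
cohens_kappa <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop_config("confusion matrix must be square")
  n <- sum(cm)
  if (n <= 0) stop_config("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) return(1)
    stop_config("kappa undefined: chance agreement is 1 with imperfect agreement")
  }
  (po - pe) / (1 - pe)
}

#' Wolpaw information transfer rate
#'
#' Bits per trial `B = log2(K) + P log2(P) + (1 - P) log2((1 - P)/(K - 1))`
#' (with `0 log 0 = 0`), scaled by the trial rate. Zero at chance accuracy
#' `P = 1/K` and `log2(K) * rate` at `P = 1`.
#'
#' @param P accuracy fraction in `[0, 1]`.
#' @param K number of classes (>= 2).
#' @param trials_per_min trial rate per minute.
#' @return ITR in bits/min.
#' @export
wolpaw_itr <- function(P, K, trials_per_min) {
  assert_scalar_num(P, "P", lo = 0, hi = 1)
  K <- assert_count(K, "K", min = 2L)
  assert_scalar_num(trials_per_min, "trials_per_min", lo = 1e-12)
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  B <- log2(K) + xlx(P) + (1 - P) * log2(max((1 - P) / (K - 1), .Machine$double.xmin))
  if (P == 1) B <- log2(K)
  B * trials_per_min
}

#' Evaluate predictions against true labels
#'
#' @param y_true,y_pred integer labels.
#' @param K number of classes.
#' @param trials_per_min optional trial rate; when given, ITR is included.
#' @return an `eval_result`: confusion matrix, accuracy, kappa, ITR
#'   (`NA` without a rate), and trial count.
#' @export
evaluate <- function(y_true, y_pred, K, trials_per_min = NULL) {
  cm <- confusion(y_true, y_pred, K)
  acc <- if (sum(cm) > 0) sum(diag(cm)) / sum(cm) else NA_real_
  kap <- if (sum(cm) > 0) cohens_kappa(cm) else NA_real_
  itr <- if (!is.null(trials_per_min) && is.finite(acc))
    wolpaw_itr(acc, K, trials_per_min) else NA_real_
  structure(list(confusion = cm, accuracy = acc, kappa = kap, itr = itr,
                 n_trials = sum(cm)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n = %d, accuracy = %.3f, kappa = %.3f%s\n",
              x$n_trials, x$accuracy, x$kappa,
              if (is.finite(x$itr)) sprintf(", ITR = %.2f bits/min", x$itr) else ""))
  invisible(x)
}

#' Aggregate per-subject metric values into a table with a mean row
#'
#' Mirrors the usual per-subject results table of motor-imagery studies:
#' one row per subject, one column per method, plus a final mean row equal
#' to the column means of the unrounded values, rounded half-away-from-zero
#' to `precision` decimals.
#'
#' @param per_subject data.frame (rownames = subjects, columns = methods)
#'   or named list of named lists (subject -> method -> value).
#' @param precision decimals for the mean row.
#' @return a `subject_table`: list with `rows` (data.frame) and `mean_row`
#'   (named numeric).
#' @export
aggregate_table <- function(per_subject, precision = 2) {
  if (!is.data.frame(per_subject)) {
    subjects <- names(per_subject)
    methods <- unique(unlist(lapply(per_subject, names)))
    rows <- matrix(NA_real_, length(subjects), length(methods),
                   dimnames = list(subjects, methods))
    for (s in subjects) for (m in methods) {
      v <- per_subject[[s]][[m]]
      if (is.null(v)) stop_config("missing value for subject ", s,
                                  ", method ", m)
      rows[s, m] <- v
    }
    per_subject <- as.data.frame(rows)
  }
  if (any(is.na(per_subject)))
    stop_config("missing cells in per-subject table")
  mean_row <- vapply(per_subject, mean, numeric(1))
  mean_row <- round_half_away(mean_row, precision)
  structure(list(rows = per_subject, mean_row = mean_row,
                 precision = precision),
            class = "subject_table")
}

#' @export
print.subject_table <- function(x, ...) {
  tab <- rbind(round(x$rows, x$precision),
               Mean = x$mean_row)
  print(tab)
  invisible(x)
}

#' Write a subject table as CSV and a plain-text grid
#'
#' Emits `<stem>.csv` (per-subject rows plus the mean row) and
#' `<stem>.txt`, a fixed-width grid in the conventional
#' subjects-plus-mean layout of motor-imagery result tables.
#'
#' @param x a `subject_table` from [aggregate_table()].
#' @param stem output path without extension.
#' @return `stem`, invisibly.
#' @export
write_subject_table <- function(x, stem) {
  stopifnot(inherits(x, "subject_table"))
  tab <- rbind(round(x$rows, x$precision), Mean = x$mean_row)
  utils::write.csv(tab, paste0(stem, ".csv"))
  txt <- utils::capture.output(print(tab))
  writeLines(txt, paste0(stem, ".txt"))
  invisible(stem)
}
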