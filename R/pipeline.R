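#' Configuration for a decoding experiment grid
#'
#' Bundles every stage parameter of the simulate -> preprocess -> ORICA ->
#' CSP -> classify -> evaluate pipeline. Two sessions are generated per
#' seed: models are fitted on session 1 and evaluated on session 2
#' (adaptive classifiers adapt only during evaluation), emulating the
#' two-session design of cue-based motor-imagery recordings.
#'
#' @param sim named list of [sim_config()] overrides (e.g.
#'   `n_trials_per_class`, `snr_db`, `drift_rate`).
#' @param erd_gain ERD envelope gain for [default_sources()].
#' @param band band-pass edges in Hz.
#' @param notch_freq notch frequency in Hz, or `NULL` to skip.
#' @param epoch_window epoch window in seconds relative to the cue.
#' @param orica named list of [orica_init()] overrides plus
#'   `corr_threshold` and `line_frac` for artifact flagging.
#' @param csp_m CSP filters per class.
#' @param refine re-rank CSP filters by Fisher score of log-variance
#'   (default off: the re-ranking sharpens in-session class contrast but
#'   overfits session-specific structure and transfers worse across
#'   sessions on synthetic benchmarks).
#' @param feature_methods subset of `"CSP"`, `"ORICA-CSP"`.
#' @param classifiers subset of `"LDA"`, `"SVM"`, `"A-LDA"`, `"A-SVM"`.
#' @param th posterior acceptance threshold of the adaptive SVM.
#' @param cap working-set cap of the adaptive SVM.
#' @param eta global-mean adaptation rate of the adaptive LDA.
#' @param kernel,C,gamma,coef0 SVM kernel settings.
#' @param lda_shrinkage LDA covariance shrinkage.
#' @param trials_per_min trial rate for ITR; `NULL` derives it from the
#'   simulated trial spacing (`60 / (trial_sec + rest_sec)`).
#' @param seeds integer vector of seeds (one full run per seed).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(sim = list(), erd_gain = 0.4,
                              band = c(8, 30), notch_freq = 50,
                              epoch_window = c(0.5, 2.5),
                              orica = list(), csp_m = 2, refine = FALSE,
                              feature_methods = c("CSP", "ORICA-CSP"),
                              classifiers = c("LDA", "SVM", "A-LDA", "A-SVM"),
                              th = 0.7, cap = 500, eta = 0.05,
                              kernel = "sigmoid", C = 1, gamma = NULL, coef0 = 0,
                              lda_shrinkage = 0.01,
                              trials_per_min = NULL, seeds = 1L) {
  if (length(feature_methods) < 1 || length(classifiers) < 1)
    stop_config("need at least one feature method and one classifier")
  feature_methods <- match.arg(feature_methods, c("CSP", "ORICA-CSP"),
                               several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("LDA", "SVM", "A-LDA", "A-SVM"),
                           several.ok = TRUE)
  if (length(band) != 2 || !(band[1] < band[2]))
    stop_config("band must be (lo, hi) with lo < hi")
  cfg <- list(sim = sim, erd_gain = erd_gain, band = band,
              notch_freq = notch_freq, epoch_window = epoch_window,
              orica = orica, csp_m = csp_m, refine = isTRUE(refine),
              feature_methods = feature_methods, classifiers = classifiers,
              th = th, cap = cap, eta = eta, kernel = kernel, C = C,
              gamma = gamma, coef0 = coef0, lda_shrinkage = lda_shrinkage,
              trials_per_min = trials_per_min, seeds = as.integer(seeds))
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#' @param path YAML file whose keys are [experiment_config()] arguments.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(experiment_config, raw)
}

## FNV-1a hash of the serialized config (hex string), for run provenance
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

simulate_session <- function(config, seed, session) {
  sim_args <- config$sim
  sim_args$seed <- derive_seed(seed, paste0("session", session))
  ## same simulated subject across sessions: shared mixing, fresh sources
  sim_args$mixing_seed <- sim_args$mixing_seed %||% derive_seed(seed, "subject")
  if (session == 2) {
    probe <- do.call(sim_config, config$sim[setdiff(names(config$sim), "seed")])
    dur <- probe$n_trials_per_class * probe$n_classes *
      (probe$trial_sec + probe$rest_sec) + probe$rest_sec
    sim_args$t_start <- dur
  }
  cfg <- do.call(sim_config, sim_args)
  simulate_recording(cfg, default_sources(cfg$n_classes, config$erd_gain))
}

## notch only; the band-pass is applied after (optional) ORICA cleaning so
## the EOG reference channels still contain the low-frequency ocular signal
## the correlation criterion needs
preprocess_session <- function(config, rec) {
  if (!is.null(config$notch_freq)) rec <- notch(rec, config$notch_freq)
  rec
}

orica_clean <- function(config, rec, state = NULL) {
  oc <- config$orica
  passes <- 1L
  if (is.null(state)) {
    state <- orica_init(
      nrow(rec$data),
      schedule = forgetting_schedule(oc$u0 %||% 0.2, oc$decay_gamma %||% 0.6,
                                     oc$u_min %||% 1e-4),
      block_size = oc$block_size %||% 8,
      renormalize = oc$renormalize %||% FALSE)
    ## a fresh state gets extra convergence passes before components are judged
    passes <- oc$passes %||% 2L
  }
  for (p in seq_len(passes)) {
    res <- orica_process(state, rec)
    state <- res$state
  }
  rejected <- flag_artifact_components(
    res$activations, rec,
    corr_threshold = oc$corr_threshold %||% 0.3,
    line_frac = oc$line_frac %||% 0.5)
  list(recording = reconstruct_clean(rec, state, rejected),
       state = state, rejected = rejected)
}

extract_features <- function(config, method, train_rec, eval_rec) {
  orica_info <- NULL
  if (method == "ORICA-CSP") {
    c1 <- orica_clean(config, train_rec)
    c2 <- orica_clean(config, eval_rec, state = c1$state)
    train_rec <- c1$recording
    eval_rec <- c2$recording
    orica_info <- list(rejected_train = c1$rejected,
                       rejected_eval = c2$rejected)
  }
  train_rec <- bandpass(train_rec, config$band[1], config$band[2])
  eval_rec <- bandpass(eval_rec, config$band[1], config$band[2])
  tr_trials <- epoch(select_channels(train_rec, eeg_channels(train_rec)),
                     config$epoch_window)
  ev_trials <- epoch(select_channels(eval_rec, eeg_channels(eval_rec)),
                     config$epoch_window)
  model <- fit_csp(tr_trials, m = config$csp_m)
  if (config$refine && config$csp_m < model$n_channels)
    model <- refine_filters(model, tr_trials)
  list(train = csp_features(model, tr_trials),
       eval = csp_features(model, ev_trials),
       csp = model, orica = orica_info)
}

classify_cell <- function(config, clf, feats, K, tpm, seed) {
  tr <- feats$train; ev <- feats$eval
  adapt_log <- NULL
  preds <- switch(clf,
    "LDA" = {
      m <- train_lda(tr$features, tr$labels, shrinkage = config$lda_shrinkage)
      predict(m, ev$features)$label
    },
    "A-LDA" = {
      m <- train_lda(tr$features, tr$labels, shrinkage = config$lda_shrinkage)
      run_adaptive_lda(m, ev$features, eta = config$eta)$predictions
    },
    "SVM" = {
      m <- train_svm(tr$features, tr$labels, kernel = config$kernel,
                     C = config$C, gamma = config$gamma, coef0 = config$coef0,
                     seed = seed)
      predict(m, ev$features)$label
    },
    "A-SVM" = {
      m <- train_svm(tr$features, tr$labels, kernel = config$kernel,
                     C = config$C, gamma = config$gamma, coef0 = config$coef0,
                     seed = seed)
      st <- adaptive_state(m, th = config$th, cap = config$cap)
      ra <- run_adaptive(m, ev$features, st)
      adapt_log <- ra$log
      ra$predictions
    })
  res <- evaluate(ev$labels, preds, K, trials_per_min = tpm)
  list(result = res, adapt_log = adapt_log)
}

#' Run the full experiment grid
#'
#' For every seed: simulates a training and an evaluation session,
#' preprocesses both, and for each feature method x classifier cell fits
#' on session 1 and evaluates on session 2 (adaptive classifiers adapt,
#' unsupervised, during evaluation only). A failing cell is recorded with
#' its error message; completed cells are unaffected.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-cell progress.
#' @return a `run_record`: per-seed per-cell `eval_result`s, the mean
#'   metric grid, per-stage timings, and the config hash.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t_total <- proc.time()[["elapsed"]]
  probe <- do.call(sim_config, config$sim[setdiff(names(config$sim), "seed")])
  K <- probe$n_classes
  tpm <- config$trials_per_min %||% (60 / (probe$trial_sec + probe$rest_sec))
  cells <- expand.grid(feature = config$feature_methods,
                       classifier = config$classifiers,
                       stringsAsFactors = FALSE)
  runs <- list()
  timings <- list()
  for (seed in config$seeds) {
    t0 <- proc.time()[["elapsed"]]
    s1 <- simulate_session(config, seed, 1)
    s2 <- simulate_session(config, seed, 2)
    r1 <- preprocess_session(config, s1$recording)
    r2 <- preprocess_session(config, s2$recording)
    t_pre <- proc.time()[["elapsed"]]
    feats_by_method <- list()
    for (fm in unique(cells$feature)) {
      feats_by_method[[fm]] <- tryCatch(
        extract_features(config, fm, r1, r2),
        error = function(e) e)
    }
    t_feat <- proc.time()[["elapsed"]]
    seed_res <- list()
    for (ci in seq_len(nrow(cells))) {
      fm <- cells$feature[ci]; clf <- cells$classifier[ci]
      cell_name <- paste(fm, clf, sep = "/")
      feats <- feats_by_method[[fm]]
      out <- if (inherits(feats, "error")) {
        list(error = conditionMessage(feats))
      } else {
        tryCatch(classify_cell(config, clf, feats, K, tpm, seed),
                 error = function(e) list(error = conditionMessage(e)))
      }
      seed_res[[cell_name]] <- out
      if (verbose)
        message(sprintf("seed %d %s: %s", seed, cell_name,
                        if (!is.null(out$error)) paste("ERROR", out$error)
                        else sprintf("acc %.3f", out$result$accuracy)))
    }
    runs[[as.character(seed)]] <- seed_res
    timings[[as.character(seed)]] <-
      c(simulate_preprocess = t_pre - t0, features = t_feat - t_pre,
        classify = proc.time()[["elapsed"]] - t_feat)
  }
  grid <- summarize_grid(runs, cells)
  structure(list(config = config, config_hash = config_hash(config),
                 runs = runs, grid = grid, cells = cells,
                 trials_per_min = tpm, n_classes = K,
                 timings = timings,
                 elapsed = proc.time()[["elapsed"]] - t_total),
            class = "run_record")
}

summarize_grid <- function(runs, cells) {
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell_name <- paste(cells$feature[ci], cells$classifier[ci], sep = "/")
    vals <- lapply(runs, function(r) r[[cell_name]])
    ok <- vapply(vals, function(v) is.null(v$error), TRUE)
    res <- lapply(vals[ok], `[[`, "result")
    rows[[ci]] <- data.frame(
      feature = cells$feature[ci], classifier = cells$classifier[ci],
      n_seeds = sum(ok),
      accuracy = if (any(ok)) mean(vapply(res, `[[`, 0, "accuracy")) else NA,
      kappa = if (any(ok)) mean(vapply(res, `[[`, 0, "kappa")) else NA,
      itr = if (any(ok)) mean(vapply(res, `[[`, 0, "itr")) else NA)
  }
  do.call(rbind, rows)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %d seeds x %d cells, hash %s, %.1f s\n",
              length(x$runs), nrow(x$cells), x$config_hash, x$elapsed))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Write the report files for a completed run
#'
#' Emits `grid.csv` (mean metrics per cell), one confusion-matrix CSV per
#' completed cell and seed, adaptation logs where present, and
#' `summary.json` with the config hash and per-stage timings. Regenerating
#' the report from the same record is byte-identical.
#'
#' @param record a `run_record`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
report <- function(record, dir) {
  stopifnot(inherits(record, "run_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(record$grid, file.path(dir, "grid.csv"), row.names = FALSE)
  errors <- list()
  for (seed in names(record$runs)) {
    for (cell in names(record$runs[[seed]])) {
      v <- record$runs[[seed]][[cell]]
      tag <- paste0(gsub("[/ ]", "_", cell), "_seed", seed)
      if (!is.null(v$error)) {
        errors[[tag]] <- v$error
        next
      }
      utils::write.csv(v$result$confusion,
                       file.path(dir, paste0("confusion_", tag, ".csv")),
                       row.names = FALSE)
      if (!is.null(v$adapt_log))
        utils::write.csv(v$adapt_log,
                         file.path(dir, paste0("adaptlog_", tag, ".csv")),
                         row.names = FALSE)
    }
  }
  summary <- list(config_hash = record$config_hash,
                  n_classes = record$n_classes,
                  trials_per_min = record$trials_per_min,
                  timings = record$timings,
                  errors = errors,
                  grid = record$grid)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
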