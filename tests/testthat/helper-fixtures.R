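# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

# small, fast cohort configuration (16 channels, 64 Hz)
tiny_cfg <- function(n_subjects = 8, n_trials = 24, seed = 1, ...) {
  demo_config(n_subjects = n_subjects, n_trials = n_trials, seed = seed, ...)
}

quick_sel <- function(k_folds = 5, max_features = 2, seed = 1, ...) {
  selection_config(k_folds = k_folds, max_features = max_features,
                   seed = seed, ...)
}

# wrap a plain matrix as a feature bank
mk_bank <- function(X, channels = NULL, time_ms = NULL, freq_hz = NULL,
                    normalized = TRUE) {
  p <- ncol(X)
  structure(list(
    X = X,
    descriptors = data.frame(
      channel = channels %||% paste0("F", seq_len(p)),
      time_ms = time_ms %||% seq_len(p),
      freq_hz = freq_hz %||% rep(NA_real_, p)),
    domain = "erp", normalized = normalized, subject_ids = NULL),
    class = "feature_bank")
}

# wrap an array as an erp_set
mk_erp <- function(data, time_ms, channels) {
  structure(list(data = data, time_ms = time_ms, channels = channels,
                 condition = "nogo_correct",
                 n_trials = rep(1L, dim(data)[1]), flagged = integer(0),
                 units = "uV"), class = "erp_set")
}

# direct (sample-by-sample) cross-correlation oracle for the wavelet power
cwt_oracle <- function(x, kernel, dt) {
  L <- (length(kernel) - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(ti) {
    s <- (-L):L
    tau <- ti + s
    ok <- tau >= 1 & tau <= n
    Mod(sum(x[tau[ok]] * Conj(kernel[s[ok] + L + 1])) * dt)^2
  }, numeric(1))
}

# brute-force sliding-window artifact oracle on one trial (ch x samples)
artifact_oracle <- function(trial, fs, max_diff = 200, diff_ms = 100,
                            min_act = 0.5, act_ms = 200) {
  w1 <- round(diff_ms / 1000 * fs) + 1L
  w2 <- round(act_ms / 1000 * fs) + 1L
  n <- ncol(trial)
  bad_diff <- FALSE; bad_act <- FALSE
  for (ch in seq_len(nrow(trial))) {
    for (s in seq_len(n - w1 + 1)) {
      r <- range(trial[ch, s:(s + w1 - 1)])
      if (diff(r) > max_diff) bad_diff <- TRUE
    }
    for (s in seq_len(n - w2 + 1)) {
      r <- range(trial[ch, s:(s + w2 - 1)])
      if (diff(r) < min_act) bad_act <- TRUE
    }
  }
  c(max_diff = bad_diff, low_activity = bad_act)
}

# plain sequential forward selection sharing the package evaluator
sfs_best_of_size <- function(bank, labels, cfg, candidates, folds) {
  current <- integer(0)
  out <- numeric(cfg$max_features)
  for (s in seq_len(cfg$max_features)) {
    pool <- setdiff(candidates, current)
    accs <- vapply(pool, function(j)
      svm_cv_accuracy(bank$X[, c(current, j), drop = FALSE], labels, cfg,
                      folds)$mean_accuracy, numeric(1))
    current <- c(current, pool[which.max(accs)])
    out[s] <- max(accs)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
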