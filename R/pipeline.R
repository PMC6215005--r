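#' Save an epoch cohort as a plain-text container
#'
#' Layout: `meta.json` (fs, channel names, time axis, units, subject ids)
#' plus, per subject, `<id>_epochs.csv` (a (trials * channels) x samples
#' matrix, channel varying slowest) and `<id>_labels.csv` (one condition
#' label per trial). Everything is text, so cohorts survive
#' version control and diffing; use reduced configurations for anything you
#' intend to keep.
#'
#' @param cohort an `epoch_cohort`.
#' @param path directory to create/overwrite.
#' @param subject_ids optional ids (defaults to S001...).
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path, subject_ids = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$subjects)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  meta <- list(fs = cohort$fs, channels = cohort$channels,
               time_ms = cohort$time_ms,
               time0_index = which(cohort$time_ms == 0),
               units = cohort$units, subject_ids = subject_ids)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    d <- dim(s$epochs)
    m <- matrix(aperm(s$epochs, c(3, 1, 2)), nrow = d[3])  # samples x (tr,ch)
    data.table::fwrite(data.table::as.data.table(t(m)),
                       file.path(path, paste0(subject_ids[i], "_epochs.csv")))
    data.table::fwrite(data.frame(condition = as.character(s$condition)),
                       file.path(path, paste0(subject_ids[i], "_labels.csv")))
  }
  invisible(path)
}

#' Load an epoch cohort from the plain-text container
#'
#' Validates the schema and axes; a missing metadata field raises an error
#' naming it.
#'
#' @param path directory written by [save_cohort()].
#' @return an `epoch_cohort`.
#' @export
load_cohort <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("no meta.json under ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (field in c("fs", "channels", "time_ms", "units", "subject_ids"))
    if (is.null(meta[[field]])) stop("cohort schema error: missing '",
                                     field, "'")
  time_ms <- as.numeric(meta$time_ms)
  if (is.unsorted(time_ms, strictly = TRUE) || !any(time_ms == 0))
    stop("cohort schema error: time axis must increase strictly and contain 0")
  n_ch <- length(meta$channels)
  n_samp <- length(time_ms)
  subjects <- lapply(meta$subject_ids, function(id) {
    m <- as.matrix(data.table::fread(
      file.path(path, paste0(id, "_epochs.csv"))))
    lab <- data.table::fread(file.path(path, paste0(id, "_labels.csv")))
    n_trials <- nrow(m) / n_ch
    if (n_trials != round(n_trials) || ncol(m) != n_samp)
      stop("cohort schema error: epoch matrix of ", id,
           " does not match channels x samples")
    if (nrow(lab) != n_trials)
      stop("cohort schema error: label count of ", id,
           " does not match trial count")
    epochs <- aperm(array(t(m), dim = c(n_samp, n_trials, n_ch)), c(2, 3, 1))
    list(epochs = epochs,
         condition = factor(lab$condition,
                            levels = c("go_correct", "go_miss",
                                       "nogo_correct", "nogo_fa")),
         time_ms = time_ms, channels = meta$channels, fs = meta$fs,
         units = meta$units)
  })
  structure(list(subjects = subjects, channels = meta$channels,
                 fs = meta$fs, time_ms = time_ms, units = meta$units),
            class = "epoch_cohort")
}

#' Run the full decoding pipeline on a synthetic cohort
#'
#' Streams subject by subject (generate, artifact rejection, current source
#' density, baseline correction, correct-Nogo ERP averaging and Morlet total
#' power), then forms the behavior table, exclusions and the median-split
#' groups, builds and z-scores the ERP and/or TF feature banks, runs the
#' hybrid t-test + SFFS + SVM selection, and (optionally) the
#' train/validation + permutation + ablation verification.
#'
#' In `"paper"` mode normalization and selection use the full analysis set
#' (the reproduction protocol); the verification stage always selects on the
#' training subjects only. `"nested"` mode additionally reports
#' [nested_cv_accuracy()] for each domain, where normalization and selection
#' are re-run inside every training fold.
#'
#' @param cfg a [sim_config()].
#' @param sel_cfg a [selection_config()].
#' @param csd a [csd_params()].
#' @param freqs wavelet frequencies (default 1:18).
#' @param domains `"erp"`, `"tf"` or both.
#' @param mode `"paper"` or `"nested"`.
#' @param validate run the verification stage (default TRUE).
#' @param n_perm permutations in the verification stage.
#' @param seed master seed for split/permutation substreams (defaults to
#'   `cfg$seed`).
#' @param progress print per-stage progress lines.
#' @return object of class `decode_run`: `behavior`, `groups`, `banks`,
#'   `selection` (per domain), `validation` (per domain, if requested),
#'   `nested` (per domain, in nested mode), `manifest`, `config` pieces.
#' @export
run_pipeline <- function(cfg, sel_cfg = selection_config(),
                         csd = csd_params(), freqs = 1:18,
                         domains = c("erp", "tf"),
                         mode = c("paper", "nested"), validate = TRUE,
                         n_perm = 1000, seed = NULL, progress = FALSE) {
  mode <- match.arg(mode)
  domains <- match.arg(domains, several.ok = TRUE)
  if (is.null(seed)) seed <- cfg$seed
  say <- function(...) if (progress) message(sprintf(...))
  if (1 - cfg$go_fraction <= 0)
    stop("no Nogo trials in this configuration; Nogo decoding undefined")

  man <- cohort_manifest(cfg)
  time_ms <- epoch_time_ms(cfg)
  n_sub <- cfg$n_subjects
  n_ch <- length(cfg$channels)
  n_samp <- length(time_ms)
  M <- csd_matrix(electrode_positions(cfg$channels), csd)
  kernels <- lapply(freqs, function(f)
    morlet_kernel(morlet_params(f), cfg$fs))
  want_tf <- "tf" %in% domains

  erp <- array(NA_real_, dim = c(n_sub, n_ch, n_samp))
  tfp <- if (want_tf)
    array(NA_real_, dim = c(n_sub, length(freqs), n_ch, n_samp)) else NULL
  rows <- vector("list", n_sub)
  n_nogo <- integer(n_sub)
  say("simulating + preprocessing %d subjects", n_sub)
  for (i in seq_len(n_sub)) {
    s <- generate_subject(cfg, man$score[i], man$subject_seed[i])
    s <- reject_artifact_trials(s)$subject
    s <- apply_csd(s, M)
    s <- baseline_correct(s)
    rows[[i]] <- cbind(data.frame(subject_id = man$subject_id[i]),
                       s$behavior)
    sel <- which(s$condition == "nogo_correct")
    n_nogo[i] <- length(sel)
    if (length(sel) == 0) next
    epo <- s$epochs[sel, , , drop = FALSE]
    erp[i, , ] <- colMeans(epo)   # mean over trials (first dim)
    if (want_tf)
      tfp[i, , , ] <- subject_total_power(epo, kernels, cfg$fs)
  }

  say("behavior: exclusions + median split")
  behavior <- apply_exclusions(behavior_table(do.call(rbind, rows)))
  behavior$excluded <- behavior$excluded | n_nogo == 0
  groups <- median_split(behavior)
  keep <- match(groups$assignment$subject_id, behavior$subject_id)
  labels <- groups$assignment$group

  flagged <- integer(0)
  erp_set <- structure(list(data = erp[keep, , , drop = FALSE],
                            time_ms = time_ms, channels = cfg$channels,
                            condition = "nogo_correct",
                            n_trials = n_nogo[keep], flagged = flagged,
                            units = "uV/m^2"),
                       class = "erp_set")
  banks <- list()
  if ("erp" %in% domains)
    banks$erp <- zscore_features(build_erp_features(
      erp_set, subject_ids = groups$assignment$subject_id))
  if (want_tf) {
    tfr_set <- structure(list(power = tfp[keep, , , , drop = FALSE],
                              freqs = freqs, time_ms = time_ms,
                              channels = cfg$channels,
                              valid = edge_valid_mask(freqs, time_ms),
                              n_trials = n_nogo[keep], flagged = flagged,
                              condition = "nogo_correct"),
                         class = "tfr_set")
    banks$tf <- zscore_features(build_tf_features(
      tfr_set, subject_ids = groups$assignment$subject_id))
  }

  selection <- list()
  validation <- list()
  nested <- list()
  for (dom in domains) {
    say("selection (%s bank: %d features)", dom, ncol(banks[[dom]]$X))
    selection[[dom]] <- sffs(banks[[dom]], labels, sel_cfg)
    if (validate) {
      say("verification (%s)", dom)
      validation[[dom]] <- run_validation(banks[[dom]], labels, sel_cfg,
                                          n_perm = n_perm, seed = seed)
    }
    if (mode == "nested")
      nested[[dom]] <- nested_cv_accuracy(banks[[dom]], labels, sel_cfg)
  }
  structure(list(behavior = behavior, groups = groups, banks = banks,
                 selection = selection, validation = validation,
                 nested = nested, manifest = man, mode = mode, seed = seed,
                 sim_config = cfg, selection_config = sel_cfg),
            class = "decode_run")
}

#' Nested (leakage-free) cross-validated accuracy
#'
#' For each fold: z-scoring parameters, the t-filter and the SFFS selection
#' are computed on the training portion only, and the best selected subset
#' is evaluated on the held-out fold. The mean held-out accuracy is an
#' unbiased estimate of pipeline performance, unlike the full-set
#' ("paper-mode") training criterion, which is optimistically biased by
#' selection.
#'
#' @param bank a `feature_bank` (the *unnormalized* values are recovered
#'   from the stored normalization when present; otherwise used as-is).
#' @param labels group labels.
#' @param cfg a [selection_config()]; `max_features` bounds each inner
#'   selection.
#' @return list: `fold_accuracy`, `mean_accuracy`, `per_fold_selection`.
#' @export
nested_cv_accuracy <- function(bank, labels, cfg = selection_config()) {
  labels <- as.factor(labels)
  folds <- make_folds(labels, cfg$k_folds, cfg$seed + 7L)
  acc <- numeric(max(folds))
  sel_list <- vector("list", max(folds))
  for (f in seq_len(max(folds))) {
    tr <- which(folds != f)
    te <- which(folds == f)
    tr_bank <- bank
    tr_bank$X <- bank$X[tr, , drop = FALSE]
    tr_bank$normalized <- FALSE
    tr_bank <- zscore_features(tr_bank)
    norm <- attr(tr_bank, "normalization")
    te_bank <- bank
    te_bank$X <- bank$X[te, , drop = FALSE]
    te_bank <- zscore_features(te_bank, reference = norm)
    filt <- ttest_filter(tr_bank, labels[tr], cfg$filter_alpha, cfg$t_var)
    if (!length(filt$candidates))
      filt$candidates <- which.min(filt$p_values)
    cfg_in <- cfg
    cfg_in$seed <- cfg$seed + 13L + f
    sel <- sffs(tr_bank, labels[tr], cfg_in, filter = filt)
    model <- svm_fit(tr_bank$X[, sel$selected, drop = FALSE], labels[tr],
                     cfg)
    pred <- svm_predict(model, te_bank$X[, sel$selected, drop = FALSE])
    acc[f] <- mean(pred == labels[te])
    sel_list[[f]] <- sel$selected
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       per_fold_selection = sel_list)
}

#' Export selection and verification tables
#'
#' `selection_table()` mirrors the conventional summary layout (feature
#' number, electrode, frequency for TF banks, time point in ms, mean
#' predictability, filter p-value); `validation_table()` mirrors the
#' verification layout (cumulative feature count, training accuracy,
#' validation accuracy, permutation exceedance, ablation accuracy).
#' `export_tables()` writes both (as available) for each domain of a
#' [run_pipeline()] result as CSV plus a JSON dump of the full report.
#'
#' @param sel a `selection_result`.
#' @return data.frame.
#' @export
selection_table <- function(sel) {
  tab <- sel$steps[, c("n_features", "channel", "freq_hz", "time_ms",
                       "mean_accuracy", "p_value")]
  names(tab) <- c("feature_number", "electrode", "freq_hz", "time_point_ms",
                  "mean_predictability", "p_value")
  if (all(is.na(tab$freq_hz))) tab$freq_hz <- NULL
  tab
}

#' @rdname selection_table
#' @param report a `validation_report`.
#' @export
validation_table <- function(report) {
  tab <- report$table
  names(tab) <- c("n_features", "accuracy_training", "accuracy_validation",
                  "pct_better_than_random", "accuracy_without_selected")
  tab
}

#' @rdname selection_table
#' @param run a `decode_run`.
#' @param path output directory.
#' @export
export_tables <- function(run, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (dom in names(run$selection)) {
    data.table::fwrite(selection_table(run$selection[[dom]]),
                       file.path(path, paste0("selection_", dom, ".csv")))
    if (!is.null(run$validation[[dom]]))
      data.table::fwrite(validation_table(run$validation[[dom]]),
                         file.path(path, paste0("validation_", dom, ".csv")))
  }
  data.table::fwrite(run$groups$assignment,
                     file.path(path, "groups.csv"))
  data.table::fwrite(run$behavior, file.path(path, "behavior.csv"))
  report <- list(seed = run$seed, mode = run$mode,
                 config_hash = config_hash(run$sim_config),
                 selection = lapply(run$selection, selection_table),
                 validation = lapply(run$validation, validation_table))
  jsonlite::write_json(report, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# polynomial rolling hash over the serialized configuration; stamps
# artifacts reproducibly (exact in double precision: h*31 + b < 2^53)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(
    cfg[setdiff(names(cfg), "components")]), auto_unbox = TRUE,
    digits = NA))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read and validate a pipeline run configuration (JSON)
#'
#' Top-level keys: `sim` (arguments of [sim_config()] or
#' [demo_config()] when `sim$preset == "demo"`), `selection`
#' (arguments of [selection_config()]), `csd` (arguments of [csd_params()]),
#' `freqs`, `domains`, `mode`, `n_perm`, `seed`. Unknown keys anywhere are
#' rejected before any computation.
#'
#' @param path JSON file.
#' @return list of constructed configuration objects plus scalars, ready to
#'   splice into [run_pipeline()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sim", "selection", "csd", "freqs", "domains", "mode",
             "n_perm", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  sim_args <- raw$sim %||% list()
  preset <- sim_args$preset %||% "full"
  sim_args$preset <- NULL
  check_args <- function(args, fn, what) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) stop("unknown ", what, " key(s): ",
                          paste(bad, collapse = ", "))
    args
  }
  sim_args <- check_args(sim_args, sim_config, "sim")
  cfg <- if (identical(preset, "demo")) do.call(demo_config, sim_args)
         else do.call(sim_config, sim_args)
  sel <- do.call(selection_config,
                 check_args(raw$selection %||% list(), selection_config,
                            "selection"))
  csd <- do.call(csd_params,
                 check_args(raw$csd %||% list(), csd_params, "csd"))
  list(cfg = cfg, sel_cfg = sel, csd = csd,
       freqs = raw$freqs %||% 1:18,
       domains = raw$domains %||% c("erp", "tf"),
       mode = raw$mode %||% "paper",
       n_perm = raw$n_perm %||% 1000,
       seed = raw$seed %||% cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
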