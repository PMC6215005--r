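#' Stratified train/validation split of subjects
#'
#' Draws a disjoint, exhaustive partition with `floor(frac * N)` training
#' subjects, stratified by group so both labels appear on both sides
#' (the conventional 70/30 protocol gives 168 / 72 at N = 240).
#'
#' @param labels two-level factor/vector, one entry per subject.
#' @param frac training fraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list: `train`, `validation` (integer subject indices).
#' @export
split_train_validation <- function(labels, frac = 0.7, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  labels <- as.factor(labels)
  n <- length(labels)
  n_train <- floor(frac * n)
  with_seed(seed, {
    train <- integer(0)
    # stratified proportional allocation, largest-remainder on the total
    per <- vapply(levels(labels), function(lv)
      sum(labels == lv), numeric(1))
    alloc <- floor(per * frac)
    short <- n_train - sum(alloc)
    if (short > 0) {
      extra <- order(-(per * frac - alloc))[seq_len(short)]
      alloc[extra] <- alloc[extra] + 1
    }
    for (i in seq_along(levels(labels))) {
      idx <- which(labels == levels(labels)[i])
      train <- c(train, idx[sample.int(length(idx))][seq_len(alloc[i])])
    }
    train <- sort(train)
    validation <- setdiff(seq_len(n), train)
    if (length(unique(labels[train])) < 2 ||
        length(unique(labels[validation])) < 2)
      stop("a group is absent from one side of the split")
    list(train = train, validation = validation)
  })
}

#' Validation-set accuracy of training-selected features
#'
#' For each cumulative feature count of a training-set selection, fits the
#' SVM on the training subjects and evaluates once on the held-out
#' validation subjects. Features must have been selected using training
#' data only for the resulting accuracies to be unbiased.
#'
#' @param bank a normalized `feature_bank` over all subjects.
#' @param labels group labels for all subjects.
#' @param selection a `selection_result` fitted on the training subjects.
#' @param split list from [split_train_validation()].
#' @param cfg a [selection_config()].
#' @return numeric vector: validation accuracy per cumulative feature count.
#' @export
validate_features <- function(bank, labels, selection, split,
                              cfg = selection_config()) {
  labels <- as.factor(labels)
  vapply(selection$best_sets, function(set) {
    if (any(set > ncol(bank$X))) stop("selected feature absent from bank")
    model <- svm_fit(bank$X[split$train, set, drop = FALSE],
                     labels[split$train], cfg)
    pred <- svm_predict(model, bank$X[split$validation, set, drop = FALSE])
    mean(pred == labels[split$validation])
  }, numeric(1))
}

#' Permutation test for a selected feature set
#'
#' Re-runs the train/evaluate protocol `n_perm` times with group labels
#' randomly reassigned over all subjects (preserving the group sizes
#' exactly) and reports the percentage of permutations in which the
#' real-label validation accuracy strictly exceeds the permuted-label one
#' (ties count as not-better). The selected features are reused across
#' permutations (re-selection per permutation is available via
#' `reselect = TRUE`, at filter level only, as a stricter non-default).
#'
#' @param bank normalized `feature_bank` over all subjects.
#' @param labels real group labels.
#' @param feature_set integer columns to use.
#' @param split list from [split_train_validation()].
#' @param cfg a [selection_config()].
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed for the label shuffles.
#' @param real_accuracy precomputed real-label validation accuracy
#'   (computed when missing).
#' @param reselect re-run the t-filter + best-single-feature selection per
#'   permutation (slow; default FALSE).
#' @return list: `exceedance_pct`, `real_accuracy`, `perm_accuracy` vector.
#' @export
permutation_test <- function(bank, labels, feature_set, split,
                             cfg = selection_config(), n_perm = 1000,
                             seed = 1L, real_accuracy = NULL,
                             reselect = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- as.factor(labels)
  if (is.null(real_accuracy)) {
    model <- svm_fit(bank$X[split$train, feature_set, drop = FALSE],
                     labels[split$train], cfg)
    pred <- svm_predict(model, bank$X[split$validation, feature_set,
                                      drop = FALSE])
    real_accuracy <- mean(pred == labels[split$validation])
  }
  n <- length(labels)
  perm_acc <- numeric(n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      pl <- labels[sample.int(n)]    # preserves group sizes exactly
      set <- feature_set
      if (reselect) {
        tb <- bank
        tb$X <- bank$X[split$train, , drop = FALSE]
        f <- ttest_filter(tb, pl[split$train], cfg$filter_alpha, cfg$t_var)
        set <- if (length(f$candidates))
          f$candidates[which.min(f$p_values[f$candidates])] else feature_set
      }
      model <- svm_fit(bank$X[split$train, set, drop = FALSE],
                       pl[split$train], cfg)
      pred <- svm_predict(model, bank$X[split$validation, set, drop = FALSE])
      perm_acc[p] <- mean(pred == pl[split$validation])
    }
  })
  list(exceedance_pct = 100 * mean(real_accuracy > perm_acc),
       real_accuracy = real_accuracy, perm_accuracy = perm_acc)
}

#' Feature-omission (ablation) accuracy
#'
#' Removes the given columns from the bank, re-runs the full
#' filter + SFFS selection protocol on the training subjects over the
#' remainder, and reports the validation-set accuracy of the re-selected
#' features. If the removed columns carried all the group signal, this
#' accuracy collapses to chance.
#'
#' @param bank normalized `feature_bank` over all subjects.
#' @param labels group labels.
#' @param omit integer columns to remove (non-empty).
#' @param split list from [split_train_validation()].
#' @param cfg a [selection_config()]; `max_features` bounds the re-selection
#'   depth (1 is typical for ablation).
#' @return list: `validation_accuracy`, `reselected` (column indices in the
#'   original bank), `selection` (the re-run `selection_result`).
#' @export
ablation <- function(bank, labels, omit, split, cfg = selection_config()) {
  if (!length(omit)) stop("nothing to ablate")
  keep <- setdiff(seq_len(ncol(bank$X)), omit)
  if (!length(keep)) stop("ablation would remove every feature")
  sub <- bank
  sub$X <- bank$X[, keep, drop = FALSE]
  sub$descriptors <- bank$descriptors[keep, , drop = FALSE]
  labels <- as.factor(labels)
  tr_bank <- sub
  tr_bank$X <- sub$X[split$train, , drop = FALSE]
  filt <- ttest_filter(tr_bank, labels[split$train], cfg$filter_alpha,
                       cfg$t_var)
  if (!length(filt$candidates)) {
    # nothing survives the filter on the remainder: fall back to the single
    # smallest-p column so an accuracy is still reported
    filt$candidates <- which.min(filt$p_values)
  }
  sel <- sffs(tr_bank, labels[split$train], cfg, filter = filt)
  acc <- validate_features(sub, labels, sel, split, cfg)
  list(validation_accuracy = acc[length(acc)],
       reselected = keep[sel$selected], selection = sel)
}

#' Full training/validation verification report
#'
#' Mirrors the add-on verification protocol: a 70/30 stratified split,
#' filter + SFFS selection on the training set, per-cumulative-feature
#' validation accuracy, a label-permutation exceedance percentage, and the
#' ablation accuracy without the selected features.
#'
#' @param bank normalized `feature_bank` over all subjects.
#' @param labels group labels.
#' @param cfg a [selection_config()].
#' @param frac training fraction (default 0.7).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed (named substreams are derived from it for the
#'   split, the fold draw and the permutations).
#' @param ablate_max re-selection depth of the ablation runs (default 1).
#' @return object of class `validation_report`: data.frame `table` with one
#'   row per cumulative feature count (`n_features`, `train_accuracy`,
#'   `validation_accuracy`, `perm_exceedance_pct`, `ablation_accuracy`),
#'   plus `selection`, `split`, `seed`.
#' @export
run_validation <- function(bank, labels, cfg = selection_config(),
                           frac = 0.7, n_perm = 1000, seed = 1L,
                           ablate_max = 1) {
  labels <- as.factor(labels)
  split <- split_train_validation(labels, frac, seed = seed + 101L)
  stopifnot(length(intersect(split$train, split$validation)) == 0,
            length(union(split$train, split$validation)) == length(labels))
  tr_bank <- bank
  tr_bank$X <- bank$X[split$train, , drop = FALSE]
  cfg_tr <- cfg
  cfg_tr$seed <- cfg$seed + 1L
  sel <- sffs(tr_bank, labels[split$train], cfg_tr)
  val_acc <- validate_features(bank, labels, sel, split, cfg)
  n_steps <- length(sel$best_sets)
  perm <- numeric(n_steps)
  abl <- numeric(n_steps)
  cfg_abl <- cfg
  cfg_abl$max_features <- ablate_max
  for (s in seq_len(n_steps)) {
    set <- sel$best_sets[[s]]
    perm[s] <- permutation_test(bank, labels, set, split, cfg,
                                n_perm = n_perm, seed = seed + 211L + s,
                                real_accuracy = val_acc[s])$exceedance_pct
    abl[s] <- ablation(bank, labels, set, split, cfg_abl)$validation_accuracy
  }
  table <- data.frame(n_features = seq_len(n_steps),
                      train_accuracy = sel$steps$mean_accuracy,
                      validation_accuracy = val_acc,
                      perm_exceedance_pct = perm,
                      ablation_accuracy = abl)
  structure(list(table = table, selection = sel, split = split,
                 seed = seed, n_perm = n_perm),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> train", length(x$split$train), "/ validation",
      length(x$split$validation), "subjects\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
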