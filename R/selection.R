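#' Configuration for hybrid filter-wrapper feature selection
#'
#' @param filter_alpha t-test filter threshold; a feature is a candidate
#'   when its between-group p-value is strictly below this (default 0.01).
#' @param k_folds folds of the cross-validated wrapper (default 10).
#' @param max_features maximum selected subset size (default 20).
#' @param svm_sigma RBF kernel width, `K(x, y) = exp(-||x - y||^2 /
#'   (2 sigma^2))` (default 5).
#' @param svm_cost soft-margin cost C (default 1; unconstrained choice,
#'   exposed for sensitivity checks).
#' @param ci_level confidence level of the fold-accuracy bounds (0.99).
#' @param t_var `"welch"` (default) or `"pooled"` two-sample t statistic.
#' @param seed integer seed for the fold draw.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(filter_alpha = 0.01, k_folds = 10,
                             max_features = 20, svm_sigma = 5, svm_cost = 1,
                             ci_level = 0.99, t_var = c("welch", "pooled"),
                             seed = 1L) {
  stopifnot(filter_alpha > 0, filter_alpha < 1, k_folds >= 2,
            max_features >= 1, svm_sigma > 0, svm_cost > 0,
            ci_level > 0, ci_level < 1)
  structure(list(filter_alpha = filter_alpha, k_folds = as.integer(k_folds),
                 max_features = as.integer(max_features),
                 svm_sigma = svm_sigma, svm_cost = svm_cost,
                 ci_level = ci_level, t_var = match.arg(t_var),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Two-sample t-test filter over feature columns
#'
#' Computes a per-column two-sample t-test between the two groups
#' (Welch by default) and keeps columns with p strictly below `alpha`
#' ("below 0.01" is read as a strict inequality). P-values of all columns
#' are retained for reporting.
#'
#' @param bank a `feature_bank` (normalized or not; the t statistic is
#'   invariant to affine column transforms).
#' @param labels factor/vector with two levels aligned to the bank rows.
#' @param alpha threshold, default 0.01.
#' @param t_var `"welch"` or `"pooled"`.
#' @return list: `candidates` (column indices, in column order),
#'   `p_values` (all columns), `alpha`.
#' @export
ttest_filter <- function(bank, labels, alpha = 0.01,
                         t_var = c("welch", "pooled")) {
  t_var <- match.arg(t_var)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 subjects")
  p <- column_t_pvalues(bank$X, g1, g2, t_var)
  list(candidates = which(p < alpha), p_values = p, alpha = alpha)
}

column_t_pvalues <- function(X, g1, g2, t_var) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- (colMeans(X[g1, , drop = FALSE]^2) - m1^2) * n1 / (n1 - 1)
  v2 <- (colMeans(X[g2, , drop = FALSE]^2) - m2^2) * n2 / (n2 - 1)
  if (t_var == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[!is.finite(tt)] <- 1
  p
}

#' Stratified k-fold assignment
#'
#' Subjects are partitioned into k folds once per run, stratified by group
#' so every fold keeps the class balance (which also stabilizes the per-fold
#' accuracy granularity, e.g. 1/24 at N = 240 and k = 10).
#'
#' @param labels two-level factor/vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) per subject.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(tabulate(fold, k) == 0)) stop("more folds than subjects")
  fold
}

# minimal RBF C-SVC wrappers over the compiled SMO core
svm_fit <- function(X, y, cfg) {
  y <- as.factor(y)
  yy <- ifelse(y == levels(y)[2], 1, -1)
  fit <- svm_train_core(as.matrix(X), yy, cfg$svm_cost, cfg$svm_sigma)
  list(X = as.matrix(X), yy = yy, levels = levels(y),
       alpha = fit$alpha, b = fit$b, sigma = cfg$svm_sigma)
}

svm_predict <- function(model, Xnew) {
  d <- svm_decision_core(model$X, model$yy, model$alpha, model$b,
                         as.matrix(Xnew), model$sigma)
  factor(ifelse(d >= 0, model$levels[2], model$levels[1]),
         levels = model$levels)
}

#' Cross-validated SVM accuracy for a feature subset
#'
#' Trains the RBF-kernel C-SVC on k-1 folds and tests on the held-out fold,
#' for each fold, so every subject is tested exactly once. Returns the k
#' test-fold accuracies, their mean, and the per-group (classwise)
#' accuracies pooled over all held-out predictions.
#'
#' @param X numeric matrix (subjects x selected features).
#' @param labels two-level factor/vector.
#' @param cfg a [selection_config()].
#' @param folds fold ids from [make_folds()]; drawn from `cfg$seed` when
#'   missing.
#' @return list: `fold_accuracy` (length k), `mean_accuracy`,
#'   `class_accuracy` (named, per group), `folds`.
#' @export
svm_cv_accuracy <- function(X, labels, cfg = selection_config(),
                            folds = NULL) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (ncol(X) == 0) stop("empty feature subset")
  if (is.null(folds)) folds <- make_folds(labels, cfg$k_folds, cfg$seed)
  k <- max(folds)
  acc <- numeric(k)
  pred <- factor(rep(levels(labels)[1], length(labels)),
                 levels = levels(labels))
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(unique(labels[tr])) < 2)
      stop("training fold with a single class; use stratified folds")
    model <- svm_fit(X[tr, , drop = FALSE], labels[tr], cfg)
    pred[te] <- svm_predict(model, X[te, , drop = FALSE])
    acc[f] <- mean(pred[te] == labels[te])
  }
  cls <- vapply(levels(labels), function(lv)
    mean(pred[labels == lv] == lv), numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       class_accuracy = cls, folds = folds)
}

#' Student-t confidence bounds for fold accuracies
#'
#' `mean +- t[(1 + level)/2, k - 1] * sd / sqrt(k)`; zero-variance folds
#' yield a zero-width interval at the mean.
#'
#' @param fold_accuracies numeric vector (k >= 2).
#' @param level confidence level, default 0.99.
#' @return numeric c(low, high).
#' @export
confidence_bounds <- function(fold_accuracies, level = 0.99) {
  k <- length(fold_accuracies)
  if (k < 2) stop("need at least 2 fold accuracies")
  m <- mean(fold_accuracies)
  s <- stats::sd(fold_accuracies)
  if (s == 0) return(c(m, m))
  half <- stats::qt((1 + level) / 2, df = k - 1) * s / sqrt(k)
  c(m - half, m + half)
}

#' Do two confidence intervals indicate a significant difference?
#'
#' TRUE iff the closed intervals are disjoint; touching endpoints overlap
#' at a point and therefore do not count as significant.
#'
#' @param a,b numeric c(low, high).
#' @return logical.
#' @export
bounds_overlap <- function(a, b) {
  a[2] < b[1] || b[2] < a[1]
}

#' Sequential floating forward selection with an SVM wrapper
#'
#' Starting from the empty set, each step adds the candidate that maximizes
#' the mean cross-validated SVM accuracy (sequential forward selection),
#' then conditionally removes any member whose exclusion strictly improves
#' the best accuracy known for the smaller size (the backward "floating"
#' step). Folds are drawn once per run from the seed, so the procedure is
#' deterministic. Ties between candidates are broken by lower filter
#' p-value, then column order.
#'
#' @param bank a normalized `feature_bank`.
#' @param labels two-level factor/vector aligned to the bank rows.
#' @param cfg a [selection_config()].
#' @param candidates candidate column indices; defaults to the
#'   [ttest_filter()] survivors.
#' @param filter optional precomputed [ttest_filter()] result.
#' @return object of class `selection_result`: data.frame `steps` (one row
#'   per subset size: `n_features`, `feature`, `channel`, `time_ms`,
#'   `freq_hz`, `mean_accuracy`, `ci_low`, `ci_high`, `p_value`, classwise
#'   accuracy columns), `fold_accuracy` matrix (step x k), `selected`
#'   (ordered column indices), `best_sets` (per size), `folds`, `config`.
#' @export
sffs <- function(bank, labels, cfg = selection_config(), candidates = NULL,
                 filter = NULL) {
  labels <- as.factor(labels)
  if (is.null(filter))
    filter <- ttest_filter(bank, labels, cfg$filter_alpha, cfg$t_var)
  if (is.null(candidates)) candidates <- filter$candidates
  if (length(candidates) < 1) stop("no candidate features survive the filter")
  folds <- make_folds(labels, cfg$k_folds, cfg$seed)
  X <- bank$X
  pvals <- filter$p_values

  cache <- new.env(parent = emptyenv())
  evaluate <- function(set) {
    key <- paste(sort(set), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- svm_cv_accuracy(X[, set, drop = FALSE], labels, cfg, folds)
    cache[[key]] <- res
    res
  }

  max_k <- min(cfg$max_features, length(candidates))
  best_sets <- vector("list", max_k)
  best_acc <- rep(-Inf, max_k)
  best_res <- vector("list", max_k)
  record <- function(set, res) {
    s <- length(set)
    if (s >= 1 && s <= max_k && res$mean_accuracy > best_acc[s]) {
      best_acc[s] <<- res$mean_accuracy
      best_sets[[s]] <<- set
      best_res[[s]] <<- res
    }
  }

  current <- integer(0)
  while (length(current) < max_k) {
    pool <- setdiff(candidates, current)
    if (!length(pool)) break
    accs <- vapply(pool, function(j)
      evaluate(c(current, j))$mean_accuracy, numeric(1))
    ord <- order(-accs, pvals[pool], pool)
    add <- pool[ord[1]]
    current <- c(current, add)
    record(current, evaluate(current))
    # floating backward step
    while (length(current) > 2) {
      s <- length(current)
      drop_accs <- vapply(seq_along(current), function(i)
        evaluate(current[-i])$mean_accuracy, numeric(1))
      i_best <- order(-drop_accs, pvals[current], seq_along(current))[1]
      if (drop_accs[i_best] > best_acc[s - 1] &&
          current[i_best] != add) {
        current <- current[-i_best]
        record(current, evaluate(current))
      } else break
    }
  }

  sizes <- which(is.finite(best_acc))
  steps <- lapply(sizes, function(s) {
    res <- best_res[[s]]
    ci <- confidence_bounds(res$fold_accuracy, cfg$ci_level)
    newest <- setdiff(best_sets[[s]],
                      if (s > 1) best_sets[[s - 1]] else integer(0))
    feat <- if (length(newest)) newest[1] else best_sets[[s]][s]
    d <- bank$descriptors[feat, ]
    data.frame(n_features = s, feature = feat, channel = d$channel,
               time_ms = d$time_ms, freq_hz = d$freq_hz,
               mean_accuracy = res$mean_accuracy,
               ci_low = ci[1], ci_high = ci[2], p_value = pvals[feat],
               acc_low = res$class_accuracy[1],
               acc_high = res$class_accuracy[2], row.names = NULL)
  })
  steps <- do.call(rbind, steps)
  fold_acc <- t(vapply(sizes, function(s) best_res[[s]]$fold_accuracy,
                       numeric(cfg$k_folds)))
  structure(list(steps = steps, fold_accuracy = fold_acc,
                 selected = best_sets[[max(sizes)]],
                 best_sets = best_sets[sizes], folds = folds,
                 candidates = candidates, p_values = pvals, config = cfg,
                 descriptors = bank$descriptors),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", nrow(x$steps), "step(s)\n")
  print(x$steps[, c("n_features", "channel", "freq_hz", "time_ms",
                    "mean_accuracy", "p_value")], row.names = FALSE)
  invisible(x)
}
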