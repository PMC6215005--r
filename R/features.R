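#' Build the ERP (time-domain) feature bank
#'
#' One column per (channel, time point) on the post-stimulus grid from 0 to
#' `t_max_ms` inclusive at sample resolution, taken from the per-subject
#' trial-averaged correct-Nogo ERP. At 64 channels and 256 Hz this is
#' 64 x 385 = 24,640 candidate features. Subjects flagged for zero retained
#' trials are excluded from the bank with a warning.
#'
#' @param erp an `erp_set` (conventionally the correct-Nogo average).
#' @param t_max_ms end of the feature grid in ms, default 1500.
#' @param subject_ids optional ids aligned with the ERP subjects.
#' @return object of class `feature_bank`: `X` (subjects x features),
#'   `descriptors` data.frame (`channel`, `time_ms`, `freq_hz` = NA),
#'   `domain = "erp"`, `normalized`, `subject_ids`.
#' @export
build_erp_features <- function(erp, t_max_ms = 1500, subject_ids = NULL) {
  tsel <- which(erp$time_ms >= 0 & erp$time_ms <= t_max_ms)
  n_sub <- dim(erp$data)[1]
  keep <- setdiff(seq_len(n_sub), erp$flagged)
  if (length(erp$flagged))
    warning("excluding ", length(erp$flagged),
            " subject(s) without retained trials from the feature bank")
  n_ch <- length(erp$channels)
  # column order: time fastest within channel
  X <- matrix(aperm(erp$data[keep, , tsel, drop = FALSE], c(1, 3, 2)),
              nrow = length(keep))
  desc <- data.frame(
    channel = rep(erp$channels, each = length(tsel)),
    time_ms = rep(erp$time_ms[tsel], times = n_ch),
    freq_hz = NA_real_)
  new_feature_bank(X, desc, "erp", subject_ids, keep)
}

#' Build the time-frequency feature bank
#'
#' Same grid as the ERP bank, replicated for every wavelet central
#' frequency; columns whose sample falls inside the edge-invalidity margin
#' of their frequency (see [cwt_total_power()]) are omitted rather than
#' filled with boundary-contaminated power.
#'
#' @param tfr a `tfr_set` of total power.
#' @param t_max_ms end of the feature grid in ms, default 1500.
#' @param subject_ids optional ids aligned with the TFR subjects.
#' @return a `feature_bank` with `domain = "tf"` and `freq_hz` populated.
#' @export
build_tf_features <- function(tfr, t_max_ms = 1500, subject_ids = NULL) {
  tsel <- which(tfr$time_ms >= 0 & tfr$time_ms <= t_max_ms)
  n_sub <- dim(tfr$power)[1]
  keep <- setdiff(seq_len(n_sub), tfr$flagged)
  if (length(tfr$flagged))
    warning("excluding ", length(tfr$flagged),
            " subject(s) without retained trials from the feature bank")
  n_ch <- length(tfr$channels)
  nf <- length(tfr$freqs)
  # column order: time fastest, then channel, then frequency
  X <- matrix(aperm(tfr$power[keep, , , tsel, drop = FALSE], c(1, 4, 3, 2)),
              nrow = length(keep))
  desc <- data.frame(
    channel = rep(rep(tfr$channels, each = length(tsel)), times = nf),
    time_ms = rep(tfr$time_ms[tsel], times = n_ch * nf),
    freq_hz = rep(tfr$freqs, each = length(tsel) * n_ch))
  valid <- as.vector(vapply(seq_len(nf), function(f)
    rep(tfr$valid[f, tsel], times = n_ch), logical(length(tsel) * n_ch)))
  new_feature_bank(X[, valid, drop = FALSE], desc[valid, , drop = FALSE],
                   "tf", subject_ids, keep)
}

new_feature_bank <- function(X, desc, domain, subject_ids, keep) {
  rownames(desc) <- NULL
  if (!is.null(subject_ids)) subject_ids <- subject_ids[keep]
  structure(list(X = X, descriptors = desc, domain = domain,
                 normalized = FALSE, subject_ids = subject_ids,
                 subject_index = keep),
            class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> %s: %d subjects x %d features%s\n",
              x$domain, nrow(x$X), ncol(x$X),
              if (x$normalized) " (z-scored)" else ""))
  invisible(x)
}

#' Z-score normalize a feature bank
#'
#' Column-wise standardization across subjects so each feature has mean 0
#' and SD 1. The population SD (divisor N) is the default; columns with zero
#' variance are dropped with a message. When `reference` normalization
#' parameters are supplied (e.g. from the training fold in nested
#' evaluation), they are applied instead of refitting.
#'
#' @param bank a `feature_bank`.
#' @param divisor `"population"` (N, default) or `"sample"` (N - 1).
#' @param reference optional list with `center` and `scale` (and
#'   `kept` indices) as produced by a previous call (attribute
#'   `"normalization"` of the result).
#' @return normalized `feature_bank`; parameters in
#'   `attr(, "normalization")`.
#' @export
zscore_features <- function(bank, divisor = c("population", "sample"),
                            reference = NULL) {
  divisor <- match.arg(divisor)
  if (nrow(bank$X) < 2) stop("need at least 2 subjects to normalize")
  if (!is.null(reference)) {
    bank$X <- bank$X[, reference$kept, drop = FALSE]
    bank$descriptors <- bank$descriptors[reference$kept, , drop = FALSE]
    bank$X <- sweep(sweep(bank$X, 2, reference$center), 2,
                    reference$scale, "/")
    bank$normalized <- TRUE
    attr(bank, "normalization") <- reference
    return(bank)
  }
  n <- nrow(bank$X)
  ctr <- colMeans(bank$X)
  v <- colMeans(bank$X^2) - ctr^2
  v[v < 0] <- 0
  scl <- if (divisor == "population") sqrt(v) else sqrt(v * n / (n - 1))
  kept <- which(scl > 0)
  if (length(kept) < ncol(bank$X))
    message("dropping ", ncol(bank$X) - length(kept),
            " zero-variance feature column(s)")
  bank$X <- sweep(sweep(bank$X[, kept, drop = FALSE], 2, ctr[kept]), 2,
                  scl[kept], "/")
  bank$descriptors <- bank$descriptors[kept, , drop = FALSE]
  bank$normalized <- TRUE
  attr(bank, "normalization") <- list(center = ctr[kept], scale = scl[kept],
                                      kept = kept, divisor = divisor)
  bank
}

#' Look up feature columns by descriptor
#'
#' @param bank a `feature_bank`.
#' @param channel montage label (or NULL for any).
#' @param time_ms latency in ms, matched to the nearest grid point when
#'   `nearest = TRUE`, or a length-2 range.
#' @param freq_hz frequency in Hz (TF banks), exact or NULL.
#' @param nearest match `time_ms` to the closest sample instead of exactly.
#' @return integer vector of matching column indices.
#' @export
feature_lookup <- function(bank, channel = NULL, time_ms = NULL,
                           freq_hz = NULL, nearest = TRUE) {
  d <- bank$descriptors
  sel <- rep(TRUE, nrow(d))
  if (!is.null(channel)) sel <- sel & d$channel %in% channel
  if (!is.null(freq_hz)) sel <- sel & !is.na(d$freq_hz) & d$freq_hz %in% freq_hz
  if (!is.null(time_ms)) {
    if (length(time_ms) == 2) {
      sel <- sel & d$time_ms >= time_ms[1] & d$time_ms <= time_ms[2]
    } else if (nearest) {
      cand <- which(sel)
      if (!length(cand)) return(integer(0))
      best <- cand[abs(d$time_ms[cand] - time_ms) ==
                   min(abs(d$time_ms[cand] - time_ms))]
      return(best)
    } else {
      sel <- sel & d$time_ms == time_ms
    }
  }
  which(sel)
}
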