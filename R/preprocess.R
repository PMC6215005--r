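#' Automated artifact rejection for epoched data
#'
#' A trial is removed when, on any channel, any sliding window of
#' `diff_window_ms` has a peak-to-peak range above `max_diff_uV`
#' (reason `"max_diff"`), or any sliding window of `activity_window_ms` has
#' a peak-to-peak range below `min_activity_uV` (reason `"low_activity"`).
#' Both scans use step = 1 sample (the densest, most conservative reading)
#' and are applied to microvolt data, i.e. before any current source
#' density transform. The defaults are the conventional analyzer settings:
#' 200 microvolt within 100 ms, 0.5 microvolt within 200 ms.
#'
#' @param subject a single-subject record (see [generate_subject()]) or an
#'   `epoch_cohort`, in which case every subject is processed.
#' @param max_diff_uV,diff_window_ms threshold and window of the gradient
#'   criterion.
#' @param min_activity_uV,activity_window_ms threshold and window of the
#'   low-activity criterion.
#' @return for a subject: list with the filtered `subject` and a
#'   `rejection_log` data.frame (`trial`, `reason`); for a cohort: the
#'   filtered cohort with per-subject `rejection_log` attached to each
#'   subject record.
#' @export
reject_artifact_trials <- function(subject, max_diff_uV = 200,
                                   diff_window_ms = 100,
                                   min_activity_uV = 0.5,
                                   activity_window_ms = 200) {
  if (inherits(subject, "epoch_cohort")) {
    subject$subjects <- lapply(subject$subjects, function(s) {
      r <- reject_artifact_trials(s, max_diff_uV, diff_window_ms,
                                  min_activity_uV, activity_window_ms)
      s <- r$subject
      s$rejection_log <- r$rejection_log
      s
    })
    return(subject)
  }
  fs <- subject$fs
  n_samp <- dim(subject$epochs)[3]
  w_diff <- round(diff_window_ms / 1000 * fs) + 1L
  w_act <- round(activity_window_ms / 1000 * fs) + 1L
  if (w_diff > n_samp || w_act > n_samp)
    stop("rejection window longer than the epoch")
  n_ch <- dim(subject$epochs)[2]
  # samples x (channel within trial) so per-trial flags can be pooled
  x <- matrix(aperm(subject$epochs, c(3, 2, 1)), nrow = n_samp)
  flags <- artifact_scan_core(x, w_diff, w_act, max_diff_uV, min_activity_uV)
  diff_trial <- apply(matrix(flags[, 1] == 1L, nrow = n_ch), 2, any)
  act_trial <- apply(matrix(flags[, 2] == 1L, nrow = n_ch), 2, any)
  bad <- diff_trial | act_trial
  reason <- ifelse(diff_trial, "max_diff", "low_activity")[bad]
  log <- data.frame(trial = which(bad), reason = reason)
  subject$epochs <- subject$epochs[!bad, , , drop = FALSE]
  subject$condition <- subject$condition[!bad]
  list(subject = subject, rejection_log = log)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default -200 to 0 ms) so that the window mean is zero afterwards.
#'
#' @param subject single-subject record or `epoch_cohort`.
#' @param window_ms baseline window, default c(-200, 0).
#' @return the corrected record(s).
#' @export
baseline_correct <- function(subject, window_ms = c(-200, 0)) {
  if (inherits(subject, "epoch_cohort")) {
    subject$subjects <- lapply(subject$subjects, baseline_correct, window_ms)
    return(subject)
  }
  sel <- subject$time_ms >= window_ms[1] & subject$time_ms <= window_ms[2]
  if (!any(sel)) stop("empty baseline window")
  mu <- apply(subject$epochs[, , sel, drop = FALSE], c(1, 2), mean)
  subject$epochs <- subject$epochs - as.vector(mu)  # recycles over samples
  subject
}

#' Spherical-spline CSD parameters
#'
#' Order of splines `m`, maximum Legendre degree `n`, and a ridge smoothing
#' constant `lambda` added to the diagonal of the spline system (the
#' configurable stand-in for the analyzer's undocumented "precision"
#' setting). `head_radius` scales the output to current source density
#' units (1/m^2) for a spherical head of that radius in meters.
#'
#' @param m spline order (>= 2), default 4.
#' @param n maximum Legendre polynomial degree (>= m), default 10.
#' @param lambda ridge smoothing, default 1e-5.
#' @param head_radius sphere radius in m, default 1.
#' @return list of class `csd_params`.
#' @export
csd_params <- function(m = 4, n = 10, lambda = 1e-5, head_radius = 1) {
  stopifnot(m >= 2, n >= m, lambda >= 0, head_radius > 0)
  structure(list(m = m, n = n, lambda = lambda, head_radius = head_radius),
            class = "csd_params")
}

# Legendre expansion sums for the Perrin spherical-spline g and h kernels,
# evaluated at a matrix of cosines.
legendre_kernels <- function(cosang, m, nmax) {
  g <- matrix(0, nrow(cosang), ncol(cosang))
  h <- g
  p_prev <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
  p_cur <- cosang                                   # P_1
  for (deg in 1:nmax) {
    if (deg > 1) {
      p_new <- ((2 * deg - 1) * cosang * p_cur - (deg - 1) * p_prev) / deg
      p_prev <- p_cur
      p_cur <- p_new
    }
    w <- (2 * deg + 1) / (deg * (deg + 1))^m
    g <- g + w * p_cur
    h <- h + (2 * deg + 1) / (deg * (deg + 1))^(m - 1) * p_cur
  }
  list(g = g / (4 * pi), h = h / (4 * pi))
}

#' Current source density transformation matrix
#'
#' Builds the channels-by-channels linear map of the spherical-spline
#' surface Laplacian (Perrin-style): scalp potentials are interpolated with
#' the degree-truncated spline kernel `g`, and the (negated) surface
#' Laplacian is read off through the companion kernel `h`. The map
#' annihilates the constant, so the output is reference-free, in
#' potential-units per m^2.
#'
#' @param positions data.frame from [electrode_positions()] (>= 16 channels
#'   for a meaningful Laplacian; fewer are allowed but warned about).
#' @param params [csd_params()].
#' @return the transformation matrix (channels x channels).
#' @export
csd_matrix <- function(positions, params = csd_params()) {
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  xyz <- xyz / sqrt(rowSums(xyz^2))
  n_ch <- nrow(xyz)
  cosang <- tcrossprod(xyz)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-12))
    stop("duplicate electrode positions")
  if (n_ch < 16)
    warning("CSD on fewer than 16 channels is poorly conditioned")
  kern <- legendre_kernels(cosang, params$m, params$n)
  G <- kern$g + diag(params$lambda, n_ch)
  Gi <- solve(G)
  tc <- rowSums(Gi)
  Tmat <- Gi - tcrossprod(tc) / sum(tc)   # spline coefs with sum-to-zero
  (kern$h %*% Tmat) / params$head_radius^2
}

#' Apply the CSD transform to epochs
#'
#' @param subject single-subject record or `epoch_cohort`.
#' @param params [csd_params()].
#' @param positions electrode positions; defaults to the idealized spherical
#'   montage for the record's channel labels.
#' @return the transformed record(s); `units` becomes `"uV/m^2"`.
#' @export
csd_transform <- function(subject, params = csd_params(), positions = NULL) {
  if (inherits(subject, "epoch_cohort")) {
    if (is.null(positions)) positions <- electrode_positions(subject$channels)
    M <- csd_matrix(positions, params)
    subject$subjects <- lapply(subject$subjects, apply_csd, M = M)
    subject$units <- "uV/m^2"
    return(subject)
  }
  if (is.null(positions)) positions <- electrode_positions(subject$channels)
  M <- csd_matrix(positions, params)
  apply_csd(subject, M)
}

apply_csd <- function(subject, M) {
  d <- dim(subject$epochs)
  # channels x (trials*samples) multiply
  x <- matrix(aperm(subject$epochs, c(2, 1, 3)), nrow = d[2])
  y <- M %*% x
  subject$epochs <- aperm(array(y, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  subject$units <- "uV/m^2"
  subject
}

#' Average epochs into per-subject ERPs
#'
#' Averages the retained trials of one condition per subject. By default
#' only correct trials enter ("go_correct" / "nogo_correct"); subjects with
#' zero retained trials are flagged, not silently NaN-filled.
#'
#' @param cohort an `epoch_cohort`.
#' @param condition `"nogo"` or `"go"` (correct trials of that condition) or
#'   an explicit condition label.
#' @return object of class `erp_set`: `data` (subjects x channels x samples),
#'   `time_ms`, `channels`, `condition`, `n_trials` (per subject),
#'   `flagged` (subject indices with zero retained trials; their rows are NA).
#' @export
average_erp <- function(cohort, condition = c("nogo", "go")) {
  condition <- if (condition[1] %in% c("nogo", "go"))
    paste0(match.arg(condition), "_correct") else condition[1]
  subjects <- cohort$subjects
  n_sub <- length(subjects)
  n_ch <- length(cohort$channels)
  n_samp <- length(cohort$time_ms)
  data <- array(NA_real_, dim = c(n_sub, n_ch, n_samp))
  n_trials <- integer(n_sub)
  for (i in seq_len(n_sub)) {
    sel <- subjects[[i]]$condition == condition
    n_trials[i] <- sum(sel)
    if (n_trials[i] > 0)
      data[i, , ] <- colMeans(subjects[[i]]$epochs[sel, , , drop = FALSE])
  }
  flagged <- which(n_trials == 0)
  if (length(flagged))
    warning(length(flagged), " subject(s) with zero retained '",
            condition, "' trials were flagged")
  structure(list(data = data, time_ms = cohort$time_ms,
                 channels = cohort$channels, condition = condition,
                 n_trials = n_trials, flagged = flagged,
                 units = cohort$units),
            class = "erp_set")
}

#' Local-extremum peak detection in a latency window
#'
#' Finds the requested-polarity extremum inside the window that is a local
#' extremum of the waveform (larger/smaller than both neighbours). When the
#' window contains no interior local extremum (e.g. a monotone ramp), the
#' window extremum is returned and `fallback` is flagged.
#'
#' @param erp an `erp_set`.
#' @param electrode montage label.
#' @param window_ms two-element latency window in ms.
#' @param polarity `"positive"` or `"negative"`.
#' @param subject subject index (default 1).
#' @return list of class `peak_result`: `electrode`, `latency_ms`,
#'   `amplitude`, `window_ms`, `polarity`, `fallback`.
#' @export
detect_local_peak <- function(erp, electrode, window_ms,
                              polarity = c("positive", "negative"),
                              subject = 1) {
  polarity <- match.arg(polarity)
  ch <- match(electrode, erp$channels)
  if (is.na(ch)) stop("unknown electrode: ", electrode)
  stopifnot(window_ms[1] >= min(erp$time_ms), window_ms[2] <= max(erp$time_ms))
  sel <- which(erp$time_ms >= window_ms[1] & erp$time_ms <= window_ms[2])
  y <- erp$data[subject, ch, ]
  sgn <- if (polarity == "positive") 1 else -1
  yw <- sgn * y[sel]
  interior <- sel[sel > 1 & sel < length(y)]
  is_local <- vapply(interior, function(s)
    sgn * y[s] >= sgn * y[s - 1] && sgn * y[s] >= sgn * y[s + 1] &&
      (sgn * y[s] > sgn * y[s - 1] || sgn * y[s] > sgn * y[s + 1]),
    logical(1))
  if (any(is_local)) {
    cand <- interior[is_local]
    best <- cand[which.max(sgn * y[cand])]
    fallback <- FALSE
  } else {
    best <- sel[which.max(yw)]
    fallback <- TRUE
  }
  structure(list(electrode = electrode, latency_ms = erp$time_ms[best],
                 amplitude = y[best], window_ms = window_ms,
                 polarity = polarity, fallback = fallback),
            class = "peak_result")
}

#' Mean amplitude over a window, pooled over electrodes
#'
#' @param erp an `erp_set`.
#' @param electrodes one or more montage labels (pooled by averaging).
#' @param window_ms latency window in ms.
#' @return numeric vector, one mean amplitude per subject.
#' @export
mean_amplitude <- function(erp, electrodes, window_ms) {
  if (length(electrodes) == 0) stop("empty electrode list")
  ch <- match(electrodes, erp$channels)
  if (anyNA(ch)) stop("unknown electrode(s): ",
                      paste(electrodes[is.na(ch)], collapse = ", "))
  sel <- erp$time_ms >= window_ms[1] & erp$time_ms <= window_ms[2]
  if (!any(sel)) stop("empty latency window")
  apply(erp$data[, ch, sel, drop = FALSE], 1, mean)
}

#' Data-driven validation of electrode choices
#'
#' For a component's latency window, each electrode's per-subject mean
#' absolute amplitude is compared against the average of all other
#' electrodes with a paired one-sided t-test across subjects; electrodes
#' significantly larger than the rest at `alpha` are selected. The default
#' alpha is the conventional Bonferroni-corrected 0.0007 (taken verbatim,
#' not recomputed from the montage size).
#'
#' @param erp an `erp_set` (>= 3 subjects).
#' @param window_ms component latency window in ms.
#' @param alpha significance threshold, default 0.0007.
#' @return character vector of selected electrode labels (with per-electrode
#'   p-values as a `p_values` attribute).
#' @export
validate_electrode_choice <- function(erp, window_ms, alpha = 0.0007) {
  n_sub <- dim(erp$data)[1]
  n_ch <- dim(erp$data)[2]
  if (n_sub < 3) stop("need at least 3 subjects")
  if (n_ch < 2) stop("need at least 2 electrodes")
  sel <- erp$time_ms >= window_ms[1] & erp$time_ms <= window_ms[2]
  amp <- abs(apply(erp$data[, , sel, drop = FALSE], c(1, 2), mean))
  p <- vapply(seq_len(n_ch), function(e) {
    others <- rowMeans(amp[, -e, drop = FALSE])
    stats::t.test(amp[, e], others, paired = TRUE,
                  alternative = "greater")$p.value
  }, numeric(1))
  out <- erp$channels[p < alpha]
  attr(out, "p_values") <- stats::setNames(p, erp$channels)
  out
}
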