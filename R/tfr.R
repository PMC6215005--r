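#' Morlet wavelet parameters
#'
#' The complex Morlet wavelet used for the time-frequency decomposition is
#' `W(t, f0) = A * exp(-t^2 / sigma_t^2) * exp(2i * pi * f0 * t)` with
#' normalization `A = (sigma_t * sqrt(pi))^(-1/2)`, frequency width
#' `sigma_f = f0 / ratio` and time width `sigma_t = 1 / (2 * pi * sigma_f)`.
#' These closed forms are implemented verbatim (including the `sigma_t^2`
#' denominator in the Gaussian), since they reproduce the conventional
#' worked values, e.g. a spectral bandwidth `2 * sigma_f = 1.09 Hz` at
#' `f0 = 3 Hz` and a wavelet duration `2 * sigma_t = 350 ms` at `f0 = 5 Hz`
#' for the default ratio of 5.5. The identity
#' `sigma_t * sigma_f = 1 / (2 * pi)` holds exactly.
#'
#' @param f0 central frequency in Hz (> 0).
#' @param ratio dimensionless `f0 / sigma_f`, default 5.5.
#' @return list of class `morlet_params` with `f0`, `ratio`, `sigma_f` (Hz),
#'   `sigma_t` (s), `A`, and the reported resolutions `duration`
#'   (`2 * sigma_t`, s) and `bandwidth` (`2 * sigma_f`, Hz).
#' @examples
#' morlet_params(5)$duration  # 0.350 s
#' @export
morlet_params <- function(f0, ratio = 5.5) {
  if (f0 <= 0 || ratio <= 0) stop("f0 and ratio must be positive")
  sigma_f <- f0 / ratio
  sigma_t <- 1 / (2 * pi * sigma_f)
  structure(list(f0 = f0, ratio = ratio, sigma_f = sigma_f,
                 sigma_t = sigma_t, A = 1 / sqrt(sigma_t * sqrt(pi)),
                 duration = 2 * sigma_t, bandwidth = 2 * sigma_f),
            class = "morlet_params")
}

#' Sampled Morlet kernel
#'
#' Complex kernel sampled at `fs`, truncated at +-5 sigma_t (Gaussian tail
#' < 1e-5 of the peak), odd length, centre at the middle sample.
#'
#' @param params [morlet_params()].
#' @param fs sampling rate in Hz.
#' @return complex vector.
#' @export
morlet_kernel <- function(params, fs) {
  half <- ceiling(5 * params$sigma_t * fs)
  t <- (-half:half) / fs
  params$A * exp(-t^2 / params$sigma_t^2) * exp(2i * pi * params$f0 * t)
}

#' Continuous-wavelet total power
#'
#' Convolves every single trial with the complex Morlet kernel at each
#' requested central frequency, squares the magnitude, and averages across
#' trials ("total power", retaining non-phase-locked activity). Samples
#' closer than one wavelet duration (2 sigma_t) to an epoch edge are marked
#' invalid in the returned edge mask; the long +-2 s epochs exist precisely
#' to leave usable low-frequency samples around the stimulus.
#'
#' @param cohort an `epoch_cohort`.
#' @param freqs central frequencies in Hz, default `1:18` (all must be
#'   below fs/2).
#' @param condition which trials enter, as in [average_erp()].
#' @param ratio Morlet ratio `f0 / sigma_f`, default 5.5.
#' @return object of class `tfr_set`: `power` (subjects x freqs x channels x
#'   samples), `freqs`, `time_ms`, `channels`, `valid` (freqs x samples
#'   logical edge mask), `n_trials`, `flagged`.
#' @export
cwt_total_power <- function(cohort, freqs = 1:18, condition = "nogo",
                            ratio = 5.5) {
  if (any(freqs >= cohort$fs / 2))
    stop("requested frequency at or above Nyquist (fs/2)")
  cond <- if (condition[1] %in% c("nogo", "go"))
    paste0(condition[1], "_correct") else condition[1]
  kernels <- lapply(freqs, function(f)
    morlet_kernel(morlet_params(f, ratio), cohort$fs))
  n_sub <- length(cohort$subjects)
  n_ch <- length(cohort$channels)
  n_samp <- length(cohort$time_ms)
  power <- array(NA_real_, dim = c(n_sub, length(freqs), n_ch, n_samp))
  n_trials <- integer(n_sub)
  for (i in seq_len(n_sub)) {
    s <- cohort$subjects[[i]]
    sel <- which(s$condition == cond)
    n_trials[i] <- length(sel)
    if (length(sel) == 0) next
    power[i, , , ] <- subject_total_power(s$epochs[sel, , , drop = FALSE],
                                          kernels, cohort$fs)
  }
  flagged <- which(n_trials == 0)
  if (length(flagged))
    warning(length(flagged), " subject(s) with zero '", cond, "' trials")
  structure(list(power = power, freqs = freqs, time_ms = cohort$time_ms,
                 channels = cohort$channels,
                 valid = edge_valid_mask(freqs, cohort$time_ms, ratio),
                 n_trials = n_trials, flagged = flagged,
                 condition = cond),
            class = "tfr_set")
}

# trials x channels x samples -> freqs x channels x samples mean power
subject_total_power <- function(epochs, kernels, fs) {
  d <- dim(epochs)
  # samples x (trials within channel): trial index fastest
  x <- matrix(aperm(epochs, c(3, 1, 2)), nrow = d[3])
  cube <- cwt_power_core(x, kernels, d[1], d[2], 1 / fs)
  aperm(cube, c(3, 2, 1))   # -> freqs x channels x samples
}

# logical freqs x samples mask: TRUE where the sample is at least one
# wavelet duration (2 sigma_t) away from both epoch edges
edge_valid_mask <- function(freqs, time_ms, ratio = 5.5) {
  margin_ms <- vapply(freqs, function(f)
    morlet_params(f, ratio)$duration * 1000, numeric(1))
  t0 <- min(time_ms); t1 <- max(time_ms)
  out <- outer(margin_ms, time_ms,
               function(m, t) t >= t0 + m & t <= t1 - m)
  dimnames(out) <- NULL
  out
}

#' Band power over a time window and pooled electrodes
#'
#' Mean of the total power over the frequency bins inside `band_hz`, the
#' samples inside `window_ms`, and the listed (pooled) electrodes. The
#' conventional theta quantification is band 5-6 Hz, window 240-320 ms,
#' pooled FCz and Cz.
#'
#' @param tfr a `tfr_set`.
#' @param band_hz two-element frequency band in Hz (inclusive).
#' @param window_ms two-element latency window in ms (inclusive).
#' @param electrodes montage labels to pool.
#' @return numeric vector, one value per subject.
#' @export
band_power <- function(tfr, band_hz = c(5, 6), window_ms = c(240, 320),
                       electrodes = c("FCz", "Cz")) {
  fsel <- which(tfr$freqs >= band_hz[1] & tfr$freqs <= band_hz[2])
  tsel <- which(tfr$time_ms >= window_ms[1] & tfr$time_ms <= window_ms[2])
  ch <- match(electrodes, tfr$channels)
  if (anyNA(ch)) stop("unknown electrode(s): ",
                      paste(electrodes[is.na(ch)], collapse = ", "))
  if (!length(fsel) || !length(tsel) || !length(ch))
    stop("empty band/window/electrode selection")
  apply(tfr$power[, fsel, ch, tsel, drop = FALSE], 1, mean)
}
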