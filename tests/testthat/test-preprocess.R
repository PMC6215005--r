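mk_subject <- function(epochs, fs = 64, channels = NULL) {
  d <- dim(epochs)
  channels <- channels %||% paste0("ch", seq_len(d[2]))
  n <- d[3]
  time_ms <- seq(-1000, by = 1000 / fs, length.out = n)
  time_ms <- time_ms - time_ms[which.min(abs(time_ms))]
  list(epochs = epochs, condition = factor(rep("nogo_correct", d[1]),
         levels = c("go_correct", "go_miss", "nogo_correct", "nogo_fa")),
       time_ms = time_ms, channels = channels, fs = fs, units = "uV")
}

test_that("artifact rejection applies both window criteria with reasons", {
  fs <- 64
  n <- 129
  epochs <- array(0, dim = c(3, 1, n))
  t <- seq_len(n)
  epochs[1, 1, ] <- 10 * sin(2 * pi * 5 * t / fs)        # clean
  epochs[2, 1, ] <- c(rep(0, 60), rep(250, n - 60)) +
                    5 * sin(2 * pi * 5 * t / fs)          # 250 uV step
  epochs[3, 1, ] <- 0                                     # flat
  s <- mk_subject(epochs, fs)
  r <- reject_artifact_trials(s)
  expect_equal(dim(r$subject$epochs)[1], 1)
  expect_setequal(r$rejection_log$trial, c(2, 3))
  expect_equal(r$rejection_log$reason[r$rejection_log$trial == 2], "max_diff")
  expect_equal(r$rejection_log$reason[r$rejection_log$trial == 3],
               "low_activity")
  expect_error(reject_artifact_trials(s, activity_window_ms = 5000), "longer")
})

test_that("rejection agrees with a brute-force window scan and is idempotent", {
  set.seed(31)
  fs <- 64
  epochs <- array(rnorm(12 * 2 * 129, sd = 40), dim = c(12, 2, 129))
  epochs[4, 1, 60] <- 400                  # gradient artifact
  epochs[7, 2, ] <- epochs[7, 2, ] / 500   # near-flat channel
  s <- mk_subject(epochs, fs)
  r <- reject_artifact_trials(s)
  oracle_bad <- vapply(seq_len(12), function(tr)
    any(artifact_oracle(epochs[tr, , ], fs)), logical(1))
  expect_setequal(r$rejection_log$trial, which(oracle_bad))
  r2 <- reject_artifact_trials(r$subject)
  expect_equal(nrow(r2$rejection_log), 0)
  expect_identical(r2$subject$epochs, r$subject$epochs)
})

test_that("baseline correction zeroes the window and ignores offsets", {
  fs <- 64
  n <- 129
  epochs <- array(7, dim = c(1, 1, n))
  s <- mk_subject(epochs, fs)
  b <- baseline_correct(s)
  expect_equal(max(abs(b$epochs)), 0)

  set.seed(2)
  epochs2 <- array(rnorm(2 * 129), dim = c(1, 2, n))
  s2 <- mk_subject(epochs2, fs)
  s3 <- s2
  s3$epochs <- s3$epochs + 5
  expect_equal(baseline_correct(s2)$epochs, baseline_correct(s3)$epochs)

  # linear ramp: subtracted mean equals the ramp value at the window centre
  ramp <- seq(0, 10, length.out = n)
  s4 <- mk_subject(array(ramp, dim = c(1, 1, n)), fs)
  b4 <- baseline_correct(s4, c(-200, 0))
  sel <- s4$time_ms >= -200 & s4$time_ms <= 0
  expected <- ramp - mean(range(ramp[sel]))   # mean of a linear function
  expect_equal(as.vector(b4$epochs[1, 1, ]), expected, tolerance = 1e-12)
  expect_lt(abs(mean(b4$epochs[1, 1, sel])), 1e-12)
  expect_error(baseline_correct(s4, c(-5000, -4000)), "empty")
})

test_that("CSD is reference-free and annihilates uniform potentials", {
  pos <- electrode_positions(montage16())
  M <- csd_matrix(pos)
  v <- rep(4.2, 16)
  expect_lt(max(abs(M %*% v)) / 4.2, 1e-8)
  set.seed(5)
  x <- rnorm(16)
  expect_equal(as.vector(M %*% (x + 11)), as.vector(M %*% x),
               tolerance = 1e-9)
  dup <- pos
  dup[2, c("x", "y", "z")] <- dup[1, c("x", "y", "z")]
  expect_error(csd_matrix(dup), "duplicate")
  expect_error(csd_params(m = 1), "m >= 2")
})

test_that("CSD and baseline correction commute (both linear)", {
  set.seed(6)
  epochs <- array(rnorm(4 * 16 * 129), dim = c(4, 16, 129))
  s <- mk_subject(epochs, 64, montage16())
  a <- baseline_correct(csd_transform(s))
  b <- csd_transform(baseline_correct(s))
  expect_equal(a$epochs, b$epochs, tolerance = 1e-10)
})

test_that("ERP averaging handles symmetry and recovers planted templates", {
  epochs <- array(0, dim = c(2, 1, 65))
  epochs[1, 1, ] <- sin(seq_len(65) / 5)
  epochs[2, 1, ] <- epochs[1, 1, ]
  co <- structure(list(subjects = list(mk_subject(epochs, 64)),
                       channels = "ch1", fs = 64,
                       time_ms = mk_subject(epochs, 64)$time_ms,
                       units = "uV"), class = "epoch_cohort")
  e <- average_erp(co, "nogo")
  expect_equal(as.vector(e$data[1, 1, ]), as.vector(epochs[1, 1, ]))
  epochs[2, 1, ] <- -epochs[1, 1, ]
  co$subjects[[1]]$epochs <- epochs
  e2 <- average_erp(co, "nogo")
  expect_equal(max(abs(e2$data)), 0)

  # 200 noisy repetitions of a strong planted transient
  comps <- list(component_spec("Cz", 100, "transient", amplitude = 20,
                               duration_ms = 200, condition = "nogo"))
  cfg <- tiny_cfg(n_trials = 280, effect_size = 0, components = comps,
                  go_fraction = 0.3)  # mostly Nogo for this check
  s <- generate_subject(cfg, 0, seed = 12)
  co2 <- structure(list(subjects = list(s), channels = cfg$channels,
                        fs = cfg$fs, time_ms = s$time_ms, units = "uV"),
                   class = "epoch_cohort")
  avg <- average_erp(co2, "nogo")$data[1, match("Cz", cfg$channels), ]
  template <- 20 * exp(-(s$time_ms - 100)^2 / (2 * (200 / 6)^2))
  expect_gt(cor(as.vector(avg), template), 0.9)
})

test_that("local peak detection returns interior extrema or flags fallback", {
  n <- 129
  fs <- 64
  time_ms <- seq(-1000, by = 1000 / fs, length.out = n)
  time_ms <- time_ms - time_ms[which.min(abs(time_ms))]
  y <- -(time_ms - 100)^2          # parabola peaking at ~100 ms
  erp <- mk_erp(array(y, dim = c(1, 1, n)), time_ms, "Cz")
  pk <- detect_local_peak(erp, "Cz", c(90, 110), "positive")
  expect_lt(abs(pk$latency_ms - 100), 1000 / fs)
  expect_false(pk$fallback)

  erp2 <- mk_erp(array(seq_len(n), dim = c(1, 1, n)), time_ms, "Cz")
  pk2 <- detect_local_peak(erp2, "Cz", c(90, 110), "positive")
  expect_true(pk2$fallback)
  expect_equal(pk2$latency_ms,
               max(time_ms[time_ms >= 90 & time_ms <= 110]))

  # the search is confined to the requested window
  y3 <- numeric(n)
  y3[which.min(abs(time_ms - 60))] <- 100   # big peak outside the window
  y3[which.min(abs(time_ms - 100))] <- 5    # small peak inside
  erp3 <- mk_erp(array(y3, dim = c(1, 1, n)), time_ms, "PO9")
  pk3 <- detect_local_peak(erp3, "PO9", c(90, 110), "positive")
  expect_lt(abs(pk3$latency_ms - 100), 1000 / fs)
  expect_error(detect_local_peak(erp3, "XX", c(90, 110)), "unknown")
})

test_that("mean amplitude pools windows and electrodes correctly", {
  n <- 129
  time_ms <- seq(-1000, by = 1000 / 64, length.out = n)
  time_ms <- time_ms - time_ms[which.min(abs(time_ms))]
  data <- array(5, dim = c(2, 2, n))
  erp <- mk_erp(data, time_ms, c("Cz", "FC1"))
  expect_equal(mean_amplitude(erp, "Cz", c(250, 280)), c(5, 5))
  # single-sample window returns that sample
  data2 <- data
  data2[1, 1, 80] <- 42
  erp2 <- mk_erp(data2, time_ms, c("Cz", "FC1"))
  w <- time_ms[80]
  expect_equal(mean_amplitude(erp2, "Cz", c(w, w))[1], 42)
  # linear trace over the window averages to its midpoint value
  ramp <- seq(0, 128, length.out = n)
  erp3 <- mk_erp(array(rep(ramp, each = 2), dim = c(1, 2, n)),
                 time_ms, c("Cz", "FC1"))
  sel <- time_ms >= 250 & time_ms <= 280
  expect_equal(mean_amplitude(erp3, c("Cz", "FC1"), c(250, 280))[1],
               mean(range(ramp[sel])), tolerance = 1e-12)
  expect_error(mean_amplitude(erp3, character(0), c(250, 280)), "empty")
})

test_that("electrode validation selects the carrier and stays quiet on noise", {
  set.seed(44)
  n_sub <- 50
  n <- 65
  time_ms <- seq(-500, by = 1000 / 64, length.out = n)
  time_ms <- time_ms - time_ms[which.min(abs(time_ms))]
  data <- array(rnorm(n_sub * 8 * n), dim = c(n_sub, 8, n))
  win <- time_ms >= 90 & time_ms <= 110
  data[, 3, win] <- data[, 3, win] + 3      # electrode 3 carries the component
  erp <- mk_erp(data, time_ms, paste0("E", 1:8))
  selected <- validate_electrode_choice(erp, c(90, 110))
  expect_true("E3" %in% selected)
  expect_length(selected, 1)

  data0 <- array(rnorm(n_sub * 8 * n), dim = c(n_sub, 8, n))
  erp0 <- mk_erp(data0, time_ms, paste0("E", 1:8))
  expect_lte(length(validate_electrode_choice(erp0, c(90, 110))), 1)
  expect_error(validate_electrode_choice(mk_erp(data0[1:2, , , drop = FALSE],
                                                time_ms, paste0("E", 1:8)),
                                         c(90, 110)), "3 subjects")
})

test_that("electrode positions form a valid idealized montage", {
  pos <- electrode_positions(montage64())
  expect_equal(nrow(pos), 64)
  expect_equal(sqrt(rowSums(pos[, c("x", "y", "z")]^2)), rep(1, 64),
               tolerance = 1e-12)
  expect_equal(unlist(pos[pos$label == "Cz", c("x", "y", "z")]),
               c(x = 0, y = 0, z = 1), tolerance = 1e-12)
  # left/right symmetry: C3 mirrors C4 in y
  c3 <- pos[pos$label == "C3", ]
  c4 <- pos[pos$label == "C4", ]
  expect_equal(c3$y, -c4$y, tolerance = 1e-12)
  expect_gt(c3$y, 0)
  # T7 sits on the equator at the left ear
  t7 <- pos[pos$label == "T7", ]
  expect_equal(c(t7$x, t7$y, t7$z), c(0, 1, 0), tolerance = 1e-12)
  # pairwise distinct
  d <- as.matrix(dist(pos[, c("x", "y", "z")]))
  expect_gt(min(d[upper.tri(d)]), 0.05)
  expect_error(electrode_positions(c("C3", "C3")), "duplicate")
})
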