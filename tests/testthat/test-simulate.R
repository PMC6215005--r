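test_that("subject generation is reproducible and structurally sound", {
  cfg <- tiny_cfg(n_trials = 30)
  s1 <- generate_subject(cfg, score = 0.5, seed = 99)
  s2 <- generate_subject(cfg, score = 0.5, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1$epochs), c(30, 16, length(epoch_time_ms(cfg))))
  expect_equal(length(s1$condition), 30)
  expect_true(all(levels(s1$condition) ==
                  c("go_correct", "go_miss", "nogo_correct", "nogo_fa")))
  expect_true(0 %in% s1$time_ms)
  expect_true(!is.unsorted(s1$time_ms, strictly = TRUE))
  # background noise level matches the configured model
  noise_sd <- sd(s1$epochs[, match("F3", cfg$channels), ])  # no component
  target <- sqrt(cfg$noise_model$pink^2 + cfg$noise_model$white^2)
  expect_gt(noise_sd, 0.8 * target)
  expect_lt(noise_sd, 1.2 * target)
})

test_that("cohort generation obeys the trial design and fails for n < 4", {
  cfg <- tiny_cfg(n_subjects = 6, n_trials = 450, seed = 3)
  co <- generate_cohort(cfg)
  expect_length(co$cohort$subjects, 6)
  expect_true(all(vapply(co$cohort$subjects,
                         function(s) dim(s$epochs)[1], 0L) == 450))
  # 70:30 Go:Nogo in expectation, pooled over 2700 trials
  go_frac <- mean(unlist(lapply(co$cohort$subjects, function(s)
    s$condition %in% c("go_correct", "go_miss"))))
  expect_gt(go_frac, 0.67)
  expect_lt(go_frac, 0.73)
  expect_equal(nrow(co$behavior), 6)
  expect_true(all(c("score", "subject_seed") %in% names(co$manifest)))
  expect_error(generate_cohort(tiny_cfg(n_subjects = 3)), "4 subjects")
  # same master seed reproduces behavior bit for bit
  co2 <- generate_cohort(cfg)
  expect_identical(co$behavior, co2$behavior)
})

test_that("go_fraction = 1 yields zero Nogo trials and clear downstream errors", {
  expect_error(sim_config(go_fraction = 0), "go_fraction")
  cfg <- tiny_cfg(n_subjects = 4, go_fraction = 1, effect_size = 0)
  co <- generate_cohort(cfg)
  expect_true(all(vapply(co$cohort$subjects, function(s)
    sum(s$condition %in% c("nogo_correct", "nogo_fa")), 0L) == 0))
  expect_warning(average_erp(co$cohort, "nogo"), "zero retained")
  expect_error(run_pipeline(cfg, quick_sel()), "Nogo")
})

test_that("with effect_size = 0 the Nogo-minus-Go contrast at C3 is null", {
  cfg <- tiny_cfg(n_subjects = 24, n_trials = 40, effect_size = 0, seed = 17)
  c3 <- match("C3", cfg$channels)
  man <- nogodecode:::cohort_manifest(cfg)
  ts <- which.min(abs(epoch_time_ms(cfg) - 322))
  diffs <- vapply(seq_len(24), function(i) {
    s <- generate_subject(cfg, man$score[i], man$subject_seed[i])
    nogo <- s$condition == "nogo_correct"
    go <- s$condition == "go_correct"
    mean(s$epochs[nogo, c3, ts]) - mean(s$epochs[go, c3, ts])
  }, numeric(1))
  # SE of the subject-mean difference is ~0.75 uV at this scale
  expect_lt(abs(mean(diffs)), 2)
})

test_that("planted effect size calibration delivers its target", {
  # paper-scale trial counts so the behavioral readout supports d = 2
  cfg <- sim_config(n_subjects = 60, channels = montage16(), fs = 64,
                    n_trials = 450, effect_size = 2.0, seed = 42)
  co <- generate_cohort(cfg)
  bt <- behavior_table(co$behavior)
  c3 <- match("C3", cfg$channels)
  ts <- which.min(abs(co$cohort$time_ms - 322))
  v <- vapply(co$cohort$subjects, function(s)
    mean(s$epochs[s$condition == "nogo_correct", c3, ts]), numeric(1))
  g <- bt$ratio > median(bt$ratio)
  sp <- sqrt(((sum(g) - 1) * var(v[g]) + (sum(!g) - 1) * var(v[!g])) /
             (length(v) - 2))
  d <- (mean(v[g]) - mean(v[!g])) / sp
  expect_gt(d, 1.5)
  expect_lt(d, 2.5)
  # unreachable targets are rejected up front
  expect_error(demo_config(effect_size = 2.5), "ceiling")
})

test_that("a noiseless 9 Hz burst at T7 localizes to ~207 ms in total power", {
  comps <- list(component_spec("T7", 207, "oscillation", amplitude = 5,
                               duration_ms = 200, center_freq_hz = 9,
                               condition = "nogo"))
  cfg <- tiny_cfg(n_trials = 8, effect_size = 0,
                  noise_model = list(pink = 0, white = 0),
                  components = comps)
  s <- generate_subject(cfg, 0, seed = 4)
  nogo <- which(s$condition %in% c("nogo_correct", "nogo_fa"))
  kern <- list(morlet_kernel(morlet_params(9), cfg$fs))
  pow <- nogodecode:::subject_total_power(
    s$epochs[nogo, , , drop = FALSE], kern, cfg$fs)
  t7 <- match("T7", cfg$channels)
  peak_t <- s$time_ms[which.max(pow[1, t7, ])]
  expect_lt(abs(peak_t - 207), 30)
  # power is confined to the planted channel
  expect_gt(max(pow[1, t7, ]), 100 * max(pow[1, match("Cz", cfg$channels), ]))
})

test_that("planted power scales quadratically with amplitude (noiseless)", {
  pows <- vapply(c(1, 2, 4), function(a) {
    comps <- list(component_spec("T7", 207, "oscillation", amplitude = a,
                                 duration_ms = 200, center_freq_hz = 9,
                                 condition = "nogo"))
    cfg <- tiny_cfg(n_trials = 8, effect_size = 0,
                    noise_model = list(pink = 0, white = 0),
                    components = comps)
    s <- generate_subject(cfg, 0, seed = 4)
    nogo <- which(s$condition %in% c("nogo_correct", "nogo_fa"))
    kern <- list(morlet_kernel(morlet_params(9), cfg$fs))
    pow <- nogodecode:::subject_total_power(
      s$epochs[nogo, , , drop = FALSE], kern, cfg$fs)
    max(pow[1, match("T7", cfg$channels), ])
  }, numeric(1))
  expect_equal(pows[2] / pows[1], 4, tolerance = 1e-10)
  expect_equal(pows[3] / pows[1], 16, tolerance = 1e-10)
})

test_that("behavior couples monotonically to the latent score", {
  cfg <- tiny_cfg(n_subjects = 40, n_trials = 60, seed = 5)
  co <- generate_cohort(cfg)
  bt <- behavior_table(co$behavior)
  expect_gt(cor(bt$ratio, co$manifest$score), 0.5)
  expect_lt(cor(bt$fa_rate, co$manifest$score), 0)
  expect_lt(cor(bt$mean_go_rt_ms, co$manifest$score), 0)
})

test_that("component validation rejects impossible plants", {
  expect_error(tiny_cfg(components = list(
    component_spec("C3", 2500, "transient", amplitude = 1,
                   duration_ms = 50))), "outside the epoch")
  expect_error(tiny_cfg(components = list(
    component_spec("C3", 100, "oscillation", amplitude = 1,
                   duration_ms = 100, center_freq_hz = 40))), "fs")
  expect_error(component_spec("C3", 100, "transient", amplitude = 1,
                              duration_ms = -3), "duration")
  expect_error(component_spec("C3", 100, "oscillation", amplitude = 1,
                              duration_ms = 100), "center_freq_hz")
})
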