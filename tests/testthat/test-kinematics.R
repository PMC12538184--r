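test_that("angular excursion matches closed forms", {
  # constant 90 deg/s for 0.5 s -> 45 deg (trapezoid exact on constants)
  expect_equal(angular_excursion(rep(90, 51), fs = 100), 45,
               tolerance = 1e-10)
  expect_equal(angular_excursion(rep(0, 100), fs = 100), 0)
  expect_error(angular_excursion(1, fs = 100), "2 samples")
  # full open-close cycle with a 2 deg/s bias: the per-cycle linear
  # detrend removes a constant bias exactly
  t <- (0:69) / 100
  pulse <- biphasic_pulse(t, 0.05, exc = 45, d_open = 0.25, d_close = 0.25)
  expect_equal(angular_excursion(pulse + 2, fs = 100, drift_correct = TRUE),
               45, tolerance = 0.5 / 45)
})

test_that("IAV matches closed forms", {
  # constant residual 1 m/s^2 for 2 s -> 2 m/s
  expect_equal(iav(matrix(c(rep(1, 201), rep(0, 402)), ncol = 3), fs = 100),
               2, tolerance = 1e-10)
  expect_equal(iav(matrix(0, 100, 3), fs = 100), 0)
  # half-sine pulse of peak 1 m/s^2 over 1 s -> 2/pi
  tt <- seq(0, 1, by = 1e-4)
  expect_equal(iav(cbind(sin(pi * tt), 0, 0), fs = 1e4), 2 / pi,
               tolerance = 1e-6)
  # gravity baseline is removed before integrating
  acc <- cbind(0, 0, rep(9.81, 200))
  expect_equal(iav(acc, fs = 100, baseline = c(0, 0, 9.81)), 0)
})

test_that("tapping features match hand arithmetic on a constructed trial", {
  # two rectangular biphasic cycles: excursions 30 and 50 deg, opening
  # peaks 100 and 140 deg/s
  fs <- 100
  n <- 500
  g <- numeric(n)
  g[101:130] <- 100; g[131:160] <- -100    # 0.3 s at 100 -> 30 deg
  g[301:336] <- 140; g[337:372] <- -140    # ~0.357 s at 140 -> 50 deg
  g[301:336] <- 140
  rec <- make_recording(g, fs = fs)
  cycles <- data.frame(cycle = 1:2,
                       t_start = c(100, 300) / fs,
                       t_peak = c(130, 336) / fs,
                       t_end = c(160, 372) / fs)
  f <- extract_tapping_features(cycles, rec, still_s = 0)
  expect_equal(f$tap, 2)
  expect_equal(f$exc, 40, tolerance = 0.03)
  expect_equal(f$wo, 120)
  expect_equal(f$wc, 120)
})

test_that("identical cycles give zero variability features", {
  fs <- 100
  t <- (0:799) / fs
  g <- biphasic_pulse(t, 1, 40, 0.2, 0.2) + biphasic_pulse(t, 4, 40, 0.2, 0.2)
  rec <- make_recording(g, fs = fs)
  cyc <- segment_taps(g, fs)
  expect_equal(nrow(cyc), 2)
  f <- extract_tapping_features(cyc, rec, still_s = 0)
  expect_equal(f$exc_sd, 0, tolerance = 1e-8)
  expect_equal(f$wo_sd, 0, tolerance = 1e-8)
  expect_equal(f$wc_sd, 0, tolerance = 1e-8)
})

test_that("empty and single-cycle trials degrade gracefully", {
  rec <- make_recording(rep(0, 400))
  f0 <- extract_tapping_features(segment_taps(rep(0, 400), 100), rec,
                                 still_s = 0)
  expect_equal(f0$tap, 0)
  expect_true(is.na(f0$exc) && is.na(f0$wo))
  t <- (0:399) / 100
  g <- biphasic_pulse(t, 1, 40, 0.2, 0.2)
  rec1 <- make_recording(g)
  f1 <- extract_tapping_features(segment_taps(g, 100), rec1, still_s = 0)
  expect_equal(f1$tap, 1)
  expect_false(is.na(f1$exc))
  expect_true(is.na(f1$exc_sd)) # SDs undefined below 2 cycles
})

test_that("noiseless generator trials recover the configured excursion", {
  cfg <- noiseless_config(seed = 6, subject_cv = 0,
                          motor_params = rigid_motor_params(rate = 1.8,
                                                            exc = 40))
  tr <- generate_trial(generate_cohort(cfg)[1, ], "FTAP", "CL0", cfg)
  f <- extract_tapping_features(segment_trial(tr), tr$recording)
  expect_equal(f$exc, 40, tolerance = 1 / 40)
  expect_equal(f$tap, tr$truth$tap_count)
})

test_that("gait features satisfy their definitional identities", {
  cfg <- noiseless_config(seed = 12)
  tr <- generate_trial(generate_cohort(cfg)[1, ], "GAIT", "CL0", cfg)
  cyc <- segment_gait(tr$recording)
  f <- extract_gait_features(cyc, tr$recording, distance_m = 10)
  expect_equal(f$gvel * f$gt, 10, tolerance = 1e-12)
  expect_equal(f$gstrd_l, 10 / f$gstrd, tolerance = 1e-12)
  expect_equal(f$gstrd_t, f$gswt + f$gstt, tolerance = 1e-12)
  expect_true(f$grs > 0 && f$grs < 1)
  # swing excursion matches the template's drift-corrected peak angle
  expect_equal(f$gexc, tr$truth$swing_excursion,
               tolerance = 0.05)
  expect_warning(
    out <- extract_gait_features(cyc[1, , drop = FALSE], tr$recording),
    "fewer than 2")
  expect_true(all(is.na(unlist(out))))
})

test_that("the feature table has the protocol's column arithmetic", {
  dummy_records <- function(ids, exercises, cls) {
    recs <- list()
    for (id in ids) for (ex in exercises) for (cl in cls) {
      fn <- feature_names(ex)
      recs[[paste(id, ex, cl)]] <- list(
        participant_id = id, exercise = ex, cl = cl,
        features = as.list(setNames(seq_along(fn), fn)))
    }
    recs
  }
  full <- build_feature_table(dummy_records(c("a", "b"), mcdt_exercises(),
                                            mcdt_cl_levels()))
  wide <- feature_table_wide(full)
  expect_equal(ncol(wide) - 1, 180) # 45 features x 4 loads
  per_cl <- table(full$cl[full$participant_id == "a"])
  expect_true(all(per_cl == 45))
  tap_only <- build_feature_table(dummy_records("a", tapping_ex <- c("FTAP",
    "THFF", "TTHP", "HTTP"), mcdt_cl_levels()))
  expect_true(all(table(tap_only$cl) == 32)) # 8 features x 4 tasks per CL
  gait_only <- build_feature_table(dummy_records("a", "GAIT", "CL0"))
  expect_equal(nrow(gait_only), 13)
  expect_equal(nrow(build_feature_table(list())), 0)
  dup <- dummy_records("a", "FTAP", "CL0")
  expect_error(build_feature_table(c(dup, dup)), "duplicate")
})
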