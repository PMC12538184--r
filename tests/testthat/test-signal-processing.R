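test_that("Butterworth filter matches its closed-form magnitude response", {
  fs <- 100
  t <- (0:999) / fs
  # unit DC gain, everywhere
  expect_equal(butterworth_lowpass(rep(2.5, 500), fs, 5), rep(2.5, 500),
               tolerance = 1e-9)
  # 2 octaves above cutoff: |H| = (1 + (f/fc)^8)^(-1/2) per pass, squared
  y_hi <- butterworth_lowpass(sin(2 * pi * 20 * t), fs, 5)
  expect_lt(max(abs(y_hi[300:700])), 0.03)
  # deep in the passband: amplitude within 1 percent of 1
  t2 <- (0:2999) / fs
  y_lo <- butterworth_lowpass(sin(2 * pi * 0.1 * t2), fs, 5)
  expect_lt(abs(max(abs(y_lo[500:2500])) - 1), 0.01)
  expect_error(butterworth_lowpass(rep(0, 100), fs, 50), "Nyquist")
})

test_that("passband filtering is near idempotent", {
  fs <- 100
  t <- (0:2999) / fs
  x <- sin(2 * pi * 0.1 * t)
  once <- butterworth_lowpass(x, fs, 5)
  twice <- butterworth_lowpass(once, fs, 5)
  mid <- 500:2500
  expect_lt(abs(max(abs(twice[mid])) / max(abs(once[mid])) - 1), 0.02)
})

test_that("channel selection follows the exercise", {
  cfg <- cohort_config(seed = 2)
  p <- generate_cohort(cfg)[1, ]
  tr <- generate_trial(p, "FTAP", "CL0", cfg)$recording
  expect_identical(select_channel(tr), tr$gyro[, "y"])
  g <- generate_trial(p, "GAIT", "CL0", cfg)$recording
  sel <- select_channel(g)
  expect_named(sel, c("acc_x", "acc_z", "gyro_y"))
  broken <- tr
  broken$gyro <- broken$gyro[, c("x", "z")]
  expect_error(select_channel(broken), "gyro-y")
})

test_that("still-phase trimming honours its contracts", {
  x <- rnorm(1800)
  parts <- trim_still_phase(x, 100, 3)
  expect_length(parts$movement, 1500)
  expect_length(parts$still, 300)
  expect_identical(trim_still_phase(x, 100, 0)$movement, x)
  expect_error(trim_still_phase(rnorm(200), 100, 3), "shorter")
})

test_that("tap segmentation recovers the generator truth when noiseless", {
  for (seed in c(1, 2)) {
    cfg <- noiseless_config(seed = seed)
    cohort <- generate_cohort(cfg)
    for (j in c(1, 20, 44)) {
      for (ex in c("FTAP", "HTTP")) {
        tr <- generate_trial(cohort[j, ], ex, "CL0", cfg)
        cyc <- segment_trial(tr)
        expect_equal(nrow(cyc), tr$truth$tap_count)
        expect_lt(max(abs(cyc$t_peak - tr$truth$cycles$t_peak)), 1 / cfg$fs)
        # characteristic times strictly ordered within and across cycles
        expect_true(all(cyc$t_start < cyc$t_peak & cyc$t_peak < cyc$t_end))
        if (nrow(cyc) > 1) {
          expect_true(all(diff(cyc$t_start) > 0))
          expect_true(all(cyc$t_start[-1] >= cyc$t_end[-nrow(cyc)]))
        }
      }
    }
  }
})

test_that("tap segmentation handles silence and noisy single pulses", {
  expect_equal(nrow(segment_taps(rep(0, 1500), 100)), 0)
  # one biphasic pulse with 5 percent-of-peak noise: always one cycle
  t <- (0:599) / 100
  pulse <- biphasic_pulse(t, 2, exc = 40, d_open = 0.15, d_close = 0.12)
  peak <- max(pulse)
  hits <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      noisy <- pulse + rnorm(length(pulse), 0, 0.05 * peak)
      nrow(segment_taps(noisy, 100, noise_sd = 0.05 * peak))
    })
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("gait segmentation recovers stride events from the generator", {
  cfg <- noiseless_config(seed = 7)
  cohort <- generate_cohort(cfg)
  tr <- generate_trial(cohort[1, ], "GAIT", "CL0", cfg)
  cyc <- segment_gait(tr$recording)
  expect_equal(nrow(cyc), tr$truth$stride_count)
  err <- abs(as.matrix(cyc[, c("t_move", "t_toe_off", "t_heel_strike",
                               "t_flat")]) -
               as.matrix(tr$truth$cycles[, 1:4]))
  expect_lt(max(err), 2 / cfg$fs)
  expect_true(all(cyc$t_move < cyc$t_toe_off &
                    cyc$t_toe_off < cyc$t_heel_strike &
                    cyc$t_heel_strike < cyc$t_flat))
})

test_that("gait segmentation of silence warns and returns nothing", {
  cfg <- noiseless_config(seed = 7)
  quiet <- generate_trial(generate_cohort(cfg)[1, ], "GAIT", "CL0", cfg)
  quiet$recording$gyro[, "y"] <- 0
  expect_warning(out <- segment_gait(quiet$recording), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("constant-template gait gives equal strides at the set stance fraction", {
  cfg <- noiseless_config(
    seed = 10, subject_cv = 0,
    gait_params = list(
      OA = list(stride_l = 1.25, stride_t = 1.20, swing_exc = 60, stride_cv = 0),
      SCI = list(stride_l = 1.25, stride_t = 1.20, swing_exc = 60, stride_cv = 0),
      MCI = list(stride_l = 1.25, stride_t = 1.20, swing_exc = 60, stride_cv = 0)))
  tr <- generate_trial(generate_cohort(cfg)[1, ], "GAIT", "CL0", cfg)
  cyc <- segment_gait(tr$recording)
  feats <- extract_gait_features(cyc, tr$recording)
  expect_equal(feats$grs, cfg$stance_fraction, tolerance = 0.01 / 0.6)
  expect_lt(feats$gstrd_t_sd, 0.006) # within one sample period
  expect_lt(feats$gswt_sd, 0.006)
})
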