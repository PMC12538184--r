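test_that("default cohort reproduces the study's group structure", {
  cohort <- generate_cohort(cohort_config(seed = 11))
  expect_equal(as.vector(table(cohort$group)), c(10, 17, 17))
  expect_equal(nrow(cohort), 44)
  expect_true(all(cohort$fab >= 0 & cohort$fab <= 18))
  expect_true(all(cohort$mmse >= 24 & cohort$mmse <= 30))
  expect_true(all(cohort$age > 0))
})

test_that("empty and deterministic cohort contracts hold", {
  empty <- generate_cohort(cohort_config(n_per_group = c(OA = 0, SCI = 0,
                                                         MCI = 0)))
  expect_equal(nrow(empty), 0)
  a <- generate_cohort(cohort_config(seed = 42))
  b <- generate_cohort(cohort_config(seed = 42))
  expect_identical(a, b)
})

test_that("FAB scores are ordered OA > SCI > MCI in expectation", {
  cfg <- cohort_config(n_per_group = c(OA = 150, SCI = 150, MCI = 150),
                       seed = 9)
  cohort <- generate_cohort(cfg)
  m <- tapply(cohort$fab, cohort$group, mean)
  expect_gt(m[["OA"]], m[["SCI"]])
  expect_gt(m[["SCI"]], m[["MCI"]])
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(slowdown = list(OA = c(0.9, 0.8, 0.7),
                                             SCI = c(0.9, 0.8, 0.7),
                                             MCI = c(1.0, 0.9, 0.8))),
               "ordered")
  expect_error(cohort_config(slowdown = list(OA = c(1.2, 0.8, 0.7),
                                             SCI = c(0.9, 0.8, 0.7),
                                             MCI = c(0.8, 0.7, 0.6))),
               "\\(0, 1\\]")
  cfg <- cohort_config(seed = 1)
  p <- generate_cohort(cfg)[1, ]
  expect_error(generate_trial(p, "JUMP", "CL0", cfg), "exercise")
})

test_that("tapping trials have the protocol's duration and pulse structure", {
  cfg <- noiseless_config(seed = 3)
  p <- generate_cohort(cfg)[1, ]
  tr <- generate_trial(p, "FTAP", "CL0", cfg)
  expect_equal(length(tr$recording$t), 1800) # 3 s still + 15 s @ 100 Hz
  expect_equal(nrow(tr$truth$cycles), tr$truth$tap_count)
  # still phase is exactly silent without noise or drift
  expect_equal(max(abs(tr$recording$gyro[1:300, "y"])), 0)
  # integrating omega_y over one opening phase returns the per-tap excursion
  fs <- cfg$fs
  for (i in c(1, 5, tr$truth$tap_count)) {
    i1 <- round(tr$truth$cycles$t_start[i] * fs) + 1
    i2 <- round(tr$truth$cycles$t_peak[i] * fs) + 1
    got <- angular_excursion(tr$recording$gyro[i1:i2, "y"], fs)
    expect_lt(abs(got - tr$truth$cycles$excursion[i]), 0.1)
  }
})

test_that("a 2 Hz configured rate yields 30 +/- 1 taps in 15 s", {
  cfg <- noiseless_config(seed = 4, motor_params = rigid_motor_params(rate = 2),
                          subject_cv = 0)
  p <- generate_cohort(cfg)[1, ]
  tr <- generate_trial(p, "FTAP", "CL0", cfg)
  expect_true(abs(tr$truth$tap_count - 30) <= 1)
})

test_that("trial generation is deterministic and truth-consistent", {
  cfg <- cohort_config(seed = 8)
  p <- generate_cohort(cfg)[5, ]
  a <- generate_trial(p, "TTHP", "CL2", cfg)
  b <- generate_trial(p, "TTHP", "CL2", cfg)
  expect_identical(a, b)
  g <- generate_trial(p, "GAIT", "CL1", cfg)
  expect_equal(nrow(g$truth$cycles), g$truth$stride_count)
  with(g$truth$cycles, {
    expect_true(all(t_move < t_toe_off & t_toe_off < t_heel_strike &
                      t_heel_strike < t_flat))
  })
})

test_that("correct-response counts honour load, group and degenerate rates", {
  cfg <- cohort_config(seed = 5)
  p <- generate_cohort(cfg)[1, ]
  expect_error(generate_responses(p, "FTAP", "CL0", cfg), "k>0")
  expect_identical(generate_responses(p, "FTAP", "CL2", cfg),
                   generate_responses(p, "FTAP", "CL2", cfg))
  zero_cfg <- cohort_config(seed = 5,
                            response_params = list(OA = c(0, 0, 0),
                                                   SCI = c(0, 0, 0),
                                                   MCI = c(0, 0, 0)))
  expect_equal(generate_responses(p, "FTAP", "CL3", zero_cfg), 0L)
  # Monte-Carlo check of the configured ordering at the hardest load
  big <- cohort_config(n_per_group = c(OA = 200, SCI = 200, MCI = 200),
                       seed = 6)
  cohort <- generate_cohort(big)
  nc <- vapply(seq_len(nrow(cohort)), function(j) {
    generate_responses(cohort[j, ], "FTAP", "CL3", big)
  }, integer(1))
  m <- tapply(nc, cohort$group, mean)
  expect_lt(m[["MCI"]], m[["OA"]])
})

test_that("group-mean tap rate at CL3 is ordered MCI < SCI < OA", {
  cfg <- cohort_config(n_per_group = c(OA = 100, SCI = 100, MCI = 100),
                       seed = 13)
  cohort <- generate_cohort(cfg)
  rates <- vapply(seq_len(nrow(cohort)), function(j) {
    generate_trial(cohort[j, ], "FTAP", "CL3", cfg)$truth$rate_hz
  }, numeric(1))
  m <- tapply(rates, cohort$group, mean)
  expect_lt(m[["MCI"]], m[["SCI"]])
  expect_lt(m[["SCI"]], m[["OA"]])
})
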