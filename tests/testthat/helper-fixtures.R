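# Shared fixtures: all built in code, nothing on disk.

noiseless_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, noise_sd = 0, drift_rate = 0, acc_noise_sd = 0,
                ...)
}

# deterministic per-participant generator parameters switched off
rigid_motor_params <- function(rate = 2, exc = 40) {
  list(OA = list(tap_rate = rate, excursion = exc, cycle_cv = 0),
       SCI = list(tap_rate = rate, excursion = exc, cycle_cv = 0),
       MCI = list(tap_rate = rate, excursion = exc, cycle_cv = 0))
}

# run segmentation the way the pipeline does, returning cycles and truth
segment_trial <- function(trial, fs = 100, still_s = 3) {
  parts <- trim_still_phase(select_channel(trial$recording), fs, still_s)
  noise_sd <- if (length(parts$still) > 1) sd(parts$still) else 0
  segment_taps(parts$movement, fs, noise_sd = noise_sd, t0 = still_s)
}

# hand-built trial recording for unit tests of the feature extractors
make_recording <- function(gyro_y, fs = 100, exercise = "FTAP", cl = "CL0",
                           acc = NULL, still_s = 0) {
  n <- length(gyro_y)
  if (is.null(acc)) acc <- matrix(0, n, 3)
  mcdtkit:::new_trial_recording(
    "T001", exercise, cl, fs, t = (seq_len(n) - 1) / fs,
    acc = acc, gyro = cbind(0, gyro_y, 0))
}

# a raised-cosine biphasic pulse sampled at fs: opening amplitude/duration
# then closing lobe with matched integral
biphasic_pulse <- function(t, t_on, exc, d_open, d_close) {
  a_open <- 2 * exc / d_open
  a_close <- 2 * exc / d_close
  lobe <- function(tt, d) ifelse(tt >= 0 & tt <= d,
                                 0.5 * (1 - cos(2 * pi * tt / d)), 0)
  a_open * lobe(t - t_on, d_open) -
    a_close * lobe(t - (t_on + d_open), d_close)
}

# cached full-cohort pipeline run shared by structural acceptance checks
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- suppressWarnings(
      run_pipeline(run_config(cohort = cohort_config(seed = seed))))
  }
  .acceptance_cache[[key]]
}
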