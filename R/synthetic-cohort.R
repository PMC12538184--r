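#' Configuration for the synthetic MCDT cohort
#'
#' Bundles every tunable of the synthetic cohort and signal generator. The
#' defaults emulate the study conditions the analysis assumes: three
#' diagnostic groups (10 OA, 17 SCI, 17 MCI), group-ordered frontal scores
#' (OA > SCI > MCI), and a motor-cognitive interference structure in which
#' increasing cognitive load slows tapping, reduces movement amplitude,
#' increases cycle-to-cycle variability and lowers correct counting
#' responses -- more so for MCI than SCI than OA.
#'
#' @param n_per_group Named counts per diagnostic group (OA, SCI, MCI).
#' @param age_params Per-group \code{c(location, spread)} of age in years
#'   (normal draws, rounded, truncated to 50-92). Locations follow the
#'   group medians 63 / 72 / 73; spreads approximate the printed IQRs.
#' @param fab_params Per-group \code{c(location, spread)} of the Frontal
#'   Assessment Battery score (0-18), ordered OA > SCI > MCI.
#' @param mmse_params Per-group \code{c(location, spread)} of MMSE
#'   (truncated to 24-30; below 24 is an exclusion criterion).
#' @param sex_female_prob Per-group probability of female sex.
#' @param education_probs Per-group probabilities of (primary, secondary,
#'   superior) education.
#' @param motor_params Per-group base tapping rate (Hz), base angular
#'   excursion (degrees) and within-trial cycle coefficient of variation.
#' @param exercise_scale Per-exercise multipliers applied to rate and
#'   excursion (foot tapping is slower and smaller than finger tapping).
#' @param slowdown Per-group multiplicative tap-rate factors at CL1-CL3,
#'   each in (0, 1], ordered MCI <= SCI <= OA (stronger interference in
#'   MCI).
#' @param amplitude_drop Per-group multiplicative excursion factors at
#'   CL1-CL3, same ordering convention.
#' @param variability_gain Multiplicative increase of the cycle CV at
#'   CL1-CL3 (shared across groups).
#' @param response_params Per-group expected number of correct serial
#'   subtractions in the 15 s window at CL1-CL3.
#' @param response_cap Upper censoring bound for correct responses (a
#'   participant cannot utter more than ~2 responses/s).
#' @param gait_params Per-group stride length (m), stride time (s), swing
#'   angular excursion (degrees) and stride coefficient of variation.
#' @param gait_slowdown Per-group stride-time inflation factors (>= 1) at
#'   CL1-CL3.
#' @param stance_fraction Fraction of the stride spent in stance.
#' @param subject_cv Between-participant log-normal CV of motor traits.
#' @param noise_sd Gyroscope additive noise SD (degrees/s).
#' @param acc_noise_sd Accelerometer additive noise SD (m/s^2).
#' @param drift_rate Slow gyroscope bias drift ((degrees/s) per s).
#' @param fs Sampling rate (Hz).
#' @param still_s Initial still phase duration (s).
#' @param move_s Tapping movement window duration (s).
#' @param distance_m Walking distance for GAIT (m).
#' @param seed Base RNG seed; every draw is derived from it.
#'
#' @return A list of class \code{"cohort_config"}.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_per_group
#' @export
cohort_config <- function(
    n_per_group = c(OA = 10, SCI = 17, MCI = 17),
    age_params = list(OA = c(63, 6.7), SCI = c(72, 10), MCI = c(73, 9.5)),
    fab_params = list(OA = c(17, 1.0), SCI = c(15.5, 1.3), MCI = c(13.5, 1.8)),
    mmse_params = list(OA = c(29, 1.0), SCI = c(28, 1.2), MCI = c(26, 1.4)),
    sex_female_prob = c(OA = 0.60, SCI = 0.41, MCI = 0.76),
    education_probs = list(OA  = c(0.05, 0.20, 0.75),
                           SCI = c(0.06, 0.24, 0.70),
                           MCI = c(0.18, 0.35, 0.47)),
    motor_params = list(OA  = list(tap_rate = 2.0, excursion = 40, cycle_cv = 0.06),
                        SCI = list(tap_rate = 1.85, excursion = 37, cycle_cv = 0.08),
                        MCI = list(tap_rate = 1.70, excursion = 34, cycle_cv = 0.12)),
    exercise_scale = list(FTAP = c(rate = 1.00, exc = 1.00),
                          THFF = c(rate = 0.90, exc = 0.90),
                          TTHP = c(rate = 0.80, exc = 0.65),
                          HTTP = c(rate = 0.75, exc = 0.55)),
    slowdown = list(OA  = c(0.97, 0.92, 0.86),
                    SCI = c(0.94, 0.86, 0.76),
                    MCI = c(0.90, 0.78, 0.64)),
    amplitude_drop = list(OA  = c(0.98, 0.95, 0.91),
                          SCI = c(0.96, 0.90, 0.83),
                          MCI = c(0.93, 0.85, 0.74)),
    variability_gain = c(1.15, 1.30, 1.50),
    response_params = list(OA  = c(14, 9, 5.5),
                           SCI = c(13, 7.5, 4),
                           MCI = c(11, 5.5, 2.5)),
    response_cap = 30,
    gait_params = list(OA  = list(stride_l = 1.30, stride_t = 1.15, swing_exc = 65, stride_cv = 0.03),
                       SCI = list(stride_l = 1.20, stride_t = 1.25, swing_exc = 60, stride_cv = 0.04),
                       MCI = list(stride_l = 1.10, stride_t = 1.40, swing_exc = 55, stride_cv = 0.06)),
    gait_slowdown = list(OA  = c(1.03, 1.06, 1.10),
                         SCI = c(1.05, 1.10, 1.18),
                         MCI = c(1.08, 1.18, 1.32)),
    stance_fraction = 0.60,
    subject_cv = 0.10,
    noise_sd = 2,
    acc_noise_sd = 0.05,
    drift_rate = 0.2,
    fs = 100,
    still_s = 3,
    move_s = 15,
    distance_m = 10,
    seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, age_params = age_params,
    fab_params = fab_params, mmse_params = mmse_params,
    sex_female_prob = sex_female_prob, education_probs = education_probs,
    motor_params = motor_params, exercise_scale = exercise_scale,
    slowdown = slowdown, amplitude_drop = amplitude_drop,
    variability_gain = variability_gain,
    response_params = response_params, response_cap = response_cap,
    gait_params = gait_params, gait_slowdown = gait_slowdown,
    stance_fraction = stance_fraction, subject_cv = subject_cv,
    noise_sd = noise_sd, acc_noise_sd = acc_noise_sd,
    drift_rate = drift_rate, fs = fs, still_s = still_s,
    move_s = move_s, distance_m = distance_m, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  grp <- mcdt_groups()
  if (!all(grp %in% names(cfg$n_per_group))) {
    stop("n_per_group must name OA, SCI and MCI", call. = FALSE)
  }
  if (any(cfg$n_per_group < 0)) stop("group counts must be >= 0", call. = FALSE)
  for (g in grp) {
    sl <- cfg$slowdown[[g]]
    if (any(sl <= 0) || any(sl > 1)) {
      stop("slowdown factors must lie in (0, 1]", call. = FALSE)
    }
  }
  # assumed interference ordering: MCI slows at least as much as SCI, SCI
  # at least as much as OA, at every load
  for (k in 1:3) {
    if (!(cfg$slowdown$MCI[k] <= cfg$slowdown$SCI[k] &&
          cfg$slowdown$SCI[k] <= cfg$slowdown$OA[k])) {
      stop("slowdown must be ordered MCI <= SCI <= OA at each CL", call. = FALSE)
    }
  }
  if (cfg$noise_sd < 0 || cfg$drift_rate < 0) {
    stop("noise_sd and drift_rate must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic participant table
#'
#' Draws demographics and neuropsychological scores for each diagnostic
#' group. Deterministic given the config seed.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A data.frame with columns \code{id}, \code{group} (factor
#'   OA/SCI/MCI), \code{age}, \code{sex} (factor F/M), \code{education}
#'   (factor primary/secondary/superior), \code{fab} (0-18), \code{mmse}
#'   (24-30).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' table(cohort$group)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    rows <- lapply(mcdt_groups(), function(g) {
      n <- config$n_per_group[[g]]
      if (n == 0) return(NULL)
      data.frame(
        group = g,
        age = round(rnorm_trunc(n, config$age_params[[g]][1],
                                config$age_params[[g]][2], 50, 92)),
        sex = ifelse(stats::rbinom(n, 1, config$sex_female_prob[[g]]) == 1,
                     "F", "M"),
        education = sample(c("primary", "secondary", "superior"), n,
                           replace = TRUE, prob = config$education_probs[[g]]),
        fab = round(rnorm_trunc(n, config$fab_params[[g]][1],
                                config$fab_params[[g]][2], 0, 18)),
        mmse = round(rnorm_trunc(n, config$mmse_params[[g]][1],
                                 config$mmse_params[[g]][2], 24, 30)),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  })
  if (is.null(out)) {
    out <- data.frame(id = character(), group = factor(levels = mcdt_groups()),
                      age = numeric(), sex = factor(levels = c("F", "M")),
                      education = factor(levels = c("primary", "secondary", "superior")),
                      fab = numeric(), mmse = numeric())
    return(out)
  }
  out$id <- sprintf("S%03d", seq_len(nrow(out)))
  out$group <- factor(out$group, levels = mcdt_groups())
  out$sex <- factor(out$sex, levels = c("F", "M"))
  out$education <- factor(out$education,
                          levels = c("primary", "secondary", "superior"))
  out[, c("id", "group", "age", "sex", "education", "fab", "mmse")]
}

# Stable per-participant motor traits: one multiplicative factor per trait,
# shared across all of that participant's trials.
participant_traits <- function(id, config) {
  withr::with_seed(derive_seed(config$seed, "traits", id), {
    list(rate = stats::rlnorm(1, 0, config$subject_cv),
         exc = stats::rlnorm(1, 0, config$subject_cv),
         stride_l = stats::rlnorm(1, 0, config$subject_cv / 2),
         stride_t = stats::rlnorm(1, 0, config$subject_cv / 2),
         resp = stats::rlnorm(1, 0, 0.15))
  })
}

cl_index <- function(cl) {
  assert_choice(cl, mcdt_cl_levels(), "cognitive load")
  match(cl, mcdt_cl_levels()) - 1L
}

# raised-cosine lobe of unit peak over [0, d], evaluated at times tt
raised_cosine <- function(tt, d) {
  v <- numeric(length(tt))
  inside <- tt >= 0 & tt <= d
  v[inside] <- 0.5 * (1 - cos(2 * pi * tt[inside] / d))
  v
}

new_trial_recording <- function(participant_id, exercise, cl, fs, t, acc, gyro,
                                side = "dominant") {
  stopifnot(nrow(acc) == length(t), nrow(gyro) == length(t))
  colnames(acc) <- colnames(gyro) <- c("x", "y", "z")
  structure(list(participant_id = participant_id, exercise = exercise,
                 cl = cl, fs = fs, t = t, acc = acc, gyro = gyro,
                 side = side),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s %s %s: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$exercise, x$cl, length(x$t), x$fs,
              length(x$t) / x$fs))
  invisible(x)
}

#' Generate one synthetic IMU trial
#'
#' Synthesises the tri-axial accelerometer and gyroscope streams for one
#' (participant, exercise, cognitive load) trial, together with the ground
#' truth used by segmentation and feature-recovery tests.
#'
#' Tapping trials are a 3 s still phase followed by a 15 s train of
#' biphasic angular-velocity pulses on the gyroscope y axis: a positive
#' raised-cosine opening lobe followed by a negative closing lobe whose
#' integrals equal the (jittered) per-tap excursion. GAIT trials are a
#' still phase, a sequence of stride templates (negative toe-off lobe,
#' positive mid-swing lobe, negative heel-strike lobe, then a near-zero
#' stance) covering the configured distance, and a final still phase.
#' Gaussian noise and a slow linear bias drift are added to all channels.
#'
#' @param p One row of a \code{\link{generate_cohort}} table (or a list
#'   with \code{id} and \code{group}).
#' @param exercise One of \code{mcdt_exercises()}.
#' @param cl One of \code{mcdt_cl_levels()}.
#' @param config A \code{\link{cohort_config}}.
#' @return A list with elements \code{recording} (a
#'   \code{trial_recording}) and \code{truth}. For tapping, \code{truth}
#'   holds \code{cycles} (per-tap \code{t_start}, \code{t_peak},
#'   \code{t_end}, \code{excursion}), \code{tap_count} and \code{rate_hz};
#'   for GAIT it holds per-stride characteristic times, \code{stride_l_m},
#'   \code{stride_t_s}, \code{swing_excursion} (the drift-corrected peak
#'   swing angle implied by the template) and \code{gait_time_s}.
#' @examples
#' cfg <- cohort_config(seed = 2)
#' p <- generate_cohort(cfg)[1, ]
#' tr <- generate_trial(p, "FTAP", "CL0", cfg)
#' tr$truth$tap_count
#' @export
generate_trial <- function(p, exercise, cl, config = cohort_config()) {
  assert_choice(exercise, mcdt_exercises(), "exercise")
  k <- cl_index(cl)
  g <- as.character(p$group)
  assert_choice(g, mcdt_groups(), "group")
  id <- as.character(p$id)
  traits <- participant_traits(id, config)
  seed <- derive_seed(config$seed, "trial", id, exercise, cl)
  if (exercise == "GAIT") {
    generate_gait_trial(id, g, cl, k, traits, config, seed)
  } else {
    generate_tapping_trial(id, g, exercise, cl, k, traits, config, seed)
  }
}

generate_tapping_trial <- function(id, g, exercise, cl, k, traits, config, seed) {
  fs <- config$fs
  dt <- 1 / fs
  n <- round((config$still_s + config$move_s) * fs)
  t <- (seq_len(n) - 1) * dt
  mp <- config$motor_params[[g]]
  sc <- config$exercise_scale[[exercise]]
  rate <- mp$tap_rate * sc[["rate"]] * traits$rate *
    if (k > 0) config$slowdown[[g]][k] else 1
  exc <- mp$excursion * sc[["exc"]] * traits$exc *
    if (k > 0) config$amplitude_drop[[g]][k] else 1
  cv <- mp$cycle_cv * if (k > 0) config$variability_gain[k] else 1

  period <- 1 / rate
  d_open <- 0.28 * period
  d_close <- 0.22 * period
  t_end_move <- config$still_s + config$move_s

  withr::with_seed(seed, {
    starts <- peaks <- ends <- excs <- numeric(0)
    cursor <- config$still_s + stats::runif(1, 0.10, 0.30)
    repeat {
      # taps must finish comfortably inside the window so that the
      # low-pass spread of the final lobe does not straddle the boundary
      if (cursor + d_open + d_close > t_end_move - 0.20) break
      e_i <- exc * stats::rlnorm(1, 0, cv)
      starts <- c(starts, cursor)
      peaks <- c(peaks, cursor + d_open)
      ends <- c(ends, cursor + d_open + d_close)
      excs <- c(excs, e_i)
      gap <- period * stats::rlnorm(1, 0, cv)
      gap <- max(gap, 1.05 * (d_open + d_close))
      cursor <- cursor + gap
    }
    omega <- numeric(n)
    acc_burst <- numeric(n)
    for (i in seq_along(starts)) {
      a_open <- 2 * excs[i] / d_open   # lobe integral = excursion
      a_close <- 2 * excs[i] / d_close
      omega <- omega + a_open * raised_cosine(t - starts[i], d_open) -
        a_close * raised_cosine(t - peaks[i], d_close)
      # movement acceleration burst spanning the tap, scaled with amplitude
      acc_burst <- acc_burst +
        1.2 * (excs[i] / mp$excursion) * raised_cosine(t - starts[i],
                                                       d_open + d_close)
    }
    gyro <- cbind(x = stats::rnorm(n, 0, config$noise_sd),
                  y = omega + stats::rnorm(n, 0, config$noise_sd) +
                    config$drift_rate * t,
                  z = stats::rnorm(n, 0, config$noise_sd))
    acc <- cbind(x = acc_burst + stats::rnorm(n, 0, config$acc_noise_sd),
                 y = stats::rnorm(n, 0, config$acc_noise_sd),
                 z = 9.81 + stats::rnorm(n, 0, config$acc_noise_sd))
  })
  rec <- new_trial_recording(id, exercise, cl, fs, t, acc, gyro)
  truth <- list(cycles = data.frame(t_start = starts, t_peak = peaks,
                                    t_end = ends, excursion = excs),
                tap_count = length(starts), rate_hz = rate,
                excursion_deg = exc)
  list(recording = rec, truth = truth)
}

generate_gait_trial <- function(id, g, cl, k, traits, config, seed) {
  fs <- config$fs
  dt <- 1 / fs
  gp <- config$gait_params[[g]]
  stride_l <- gp$stride_l * traits$stride_l *
    if (k > 0) 1 / sqrt(config$gait_slowdown[[g]][k]) else 1
  stride_t <- gp$stride_t * traits$stride_t *
    if (k > 0) config$gait_slowdown[[g]][k] else 1
  swing_exc <- gp$swing_exc * if (k > 0) config$amplitude_drop[[g]][k] else 1
  cv <- gp$stride_cv * if (k > 0) config$variability_gain[k] else 1
  n_strides <- ceiling(config$distance_m / stride_l)

  withr::with_seed(seed, {
    stride_ts <- stride_t * stats::rlnorm(n_strides, 0, cv)
    swing_excs <- swing_exc * stats::rlnorm(n_strides, 0, cv)
    t_moves <- config$still_s + 0.2 + c(0, cumsum(stride_ts[-n_strides]))
    # template partition: swing (toe-off center to heel-strike center) is
    # (1 - stance_fraction) of the stride; flanking lobes share a width d
    swing <- (1 - config$stance_fraction) * stride_ts
    d_lobe <- pmin(0.30 * swing, 0.20)
    d_mid <- swing - d_lobe           # positive mid-swing lobe width
    t_toe_off <- t_moves + d_lobe / 2
    t_heel_strike <- t_toe_off + swing
    t_flat <- t_heel_strike + d_lobe / 2
    total_s <- max(t_flat) + config$still_s
    n <- round(total_s * fs)
    t <- (seq_len(n) - 1) * dt
    omega <- numeric(n)
    for (i in seq_len(n_strides)) {
      q <- swing_excs[i]
      # lobe integrals: -q/2, +q, -q/2 -> net shank rotation zero per stride
      a_neg <- q / d_lobe[i]
      a_mid <- 2 * q / d_mid[i]
      omega <- omega - a_neg * raised_cosine(t - t_moves[i], d_lobe[i]) +
        a_mid * raised_cosine(t - (t_moves[i] + d_lobe[i]), d_mid[i]) -
        a_neg * raised_cosine(t - (t_moves[i] + d_lobe[i] + d_mid[i]), d_lobe[i])
    }
    gyro <- cbind(x = stats::rnorm(n, 0, config$noise_sd),
                  y = omega + stats::rnorm(n, 0, config$noise_sd) +
                    config$drift_rate * t,
                  z = stats::rnorm(n, 0, config$noise_sd))
    acc <- cbind(x = stats::rnorm(n, 0, 3 * config$acc_noise_sd),
                 y = stats::rnorm(n, 0, 3 * config$acc_noise_sd),
                 z = 9.81 + stats::rnorm(n, 0, 3 * config$acc_noise_sd))
  })
  rec <- new_trial_recording(id, "GAIT", cl, fs, t, acc, gyro)
  truth <- list(cycles = data.frame(t_move = t_moves, t_toe_off = t_toe_off,
                                    t_heel_strike = t_heel_strike,
                                    t_flat = t_flat,
                                    swing_excursion = swing_excs / 2),
                stride_count = n_strides, stride_l_m = stride_l,
                stride_t_s = stride_t,
                swing_excursion = swing_exc / 2,
                gait_time_s = max(t_flat) - min(t_moves))
  list(recording = rec, truth = truth)
}

#' Simulate correct serial-subtraction responses
#'
#' Draws the number of correct counting responses Nc for one dual-task
#' trial as a censored Poisson count whose rate depends on group, load and
#' a stable participant trait. Counting only happens under dual task, so
#' CL0 is an error.
#'
#' @inheritParams generate_trial
#' @return Integer count of correct responses (>= 0).
#' @examples
#' cfg <- cohort_config(seed = 3)
#' p <- generate_cohort(cfg)[1, ]
#' generate_responses(p, "FTAP", "CL2", cfg)
#' @export
generate_responses <- function(p, exercise, cl, config = cohort_config()) {
  assert_choice(exercise, mcdt_exercises(), "exercise")
  k <- cl_index(cl)
  if (k == 0) {
    stop("correct-response counts are possible only where k>0 (no counting at CL0)",
         call. = FALSE)
  }
  g <- as.character(p$group)
  assert_choice(g, mcdt_groups(), "group")
  id <- as.character(p$id)
  traits <- participant_traits(id, config)
  rate <- config$response_params[[g]][k] * traits$resp
  withr::with_seed(derive_seed(config$seed, "nc", id, exercise, cl), {
    nc <- stats::rpois(1, rate)
  })
  as.integer(min(nc, config$response_cap))
}

#' Simulate a full study: cohort, trials and responses
#'
#' Runs the generator for every (participant, exercise, load) cell of the
#' protocol.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param exercises Subset of exercises to simulate.
#' @return A list with \code{cohort} (participant table), \code{trials}
#'   (named list of \code{generate_trial} outputs, one per cell) and
#'   \code{responses} (data.frame \code{participant_id}, \code{exercise},
#'   \code{cl}, \code{nc} for CL1-CL3).
#' @examples
#' cfg <- cohort_config(n_per_group = c(OA = 2, SCI = 2, MCI = 2), seed = 5)
#' st <- simulate_study(cfg, exercises = "FTAP")
#' length(st$trials)
#' @export
simulate_study <- function(config = cohort_config(),
                           exercises = mcdt_exercises()) {
  cohort <- generate_cohort(config)
  trials <- list()
  resp <- list()
  for (j in seq_len(nrow(cohort))) {
    p <- cohort[j, ]
    for (ex in exercises) {
      for (cl in mcdt_cl_levels()) {
        key <- paste(p$id, ex, cl, sep = "_")
        trials[[key]] <- generate_trial(p, ex, cl, config)
        if (cl != "CL0") {
          resp[[key]] <- data.frame(participant_id = p$id, exercise = ex,
                                    cl = cl,
                                    nc = generate_responses(p, ex, cl, config),
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  responses <- if (length(resp)) do.call(rbind, c(resp, make.row.names = FALSE))
               else data.frame(participant_id = character(),
                               exercise = character(), cl = character(),
                               nc = integer())
  list(cohort = cohort, trials = trials, responses = responses)
}
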