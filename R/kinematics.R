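#' Angular excursion of a movement segment
#'
#' Integrates angular velocity with the trapezoidal rule at the native
#' sample spacing and returns the peak absolute angle reached. For a full
#' open-close cycle, a per-cycle linear drift correction (zero-velocity
#' update: the angle at cycle end is forced back to the cycle-start angle)
#' removes constant gyroscope bias exactly.
#'
#' @param omega_seg Angular velocity segment (degrees/s), covering one
#'   phase or one full cycle.
#' @param fs Sampling rate (Hz).
#' @param drift_correct Apply the per-cycle linear detrend (use for full
#'   cycles, not single phases).
#' @return Peak absolute angle (degrees).
#' @examples
#' angular_excursion(rep(90, 51), fs = 100) # 90 deg/s for 0.5 s -> 45 deg
#' @export
angular_excursion <- function(omega_seg, fs, drift_correct = FALSE) {
  n <- length(omega_seg)
  if (n < 2) stop("segment must contain at least 2 samples", call. = FALSE)
  theta <- cumtrapz_dt(omega_seg, 1 / fs)
  if (drift_correct) {
    theta <- theta - seq(0, theta[n], length.out = n)
  }
  max(abs(theta))
}

#' Integral of absolute acceleration (energy-expenditure proxy)
#'
#' Trapezoidal integral of the Euclidean acceleration magnitude over the
#' movement window, after subtracting the still-phase mean acceleration
#' vector (the gravity baseline) from each channel.
#'
#' @param acc n x 3 acceleration matrix (m/s^2), movement window only.
#' @param fs Sampling rate (Hz).
#' @param baseline Length-3 gravity baseline to subtract (e.g. the
#'   still-phase column means); zeros if omitted.
#' @return IAV in m/s.
#' @examples
#' tt <- seq(0, 1, by = 1e-4)
#' a <- cbind(sin(pi * tt), 0, 0) # half-sine pulse, peak 1 m/s^2
#' iav(a, fs = 1e4)               # ~ 2 / pi
#' @export
iav <- function(acc, fs, baseline = c(0, 0, 0)) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2) return(0)
  res <- sweep(acc, 2, baseline, "-")
  mag <- sqrt(rowSums(res^2))
  trapz_dt(mag, 1 / fs)
}

#' Kinematic features of one tapping trial
#'
#' Computes the eight per-trial tapping parameters: tap count, mean and SD
#' of the per-cycle drift-corrected excursion, mean and SD of the peak
#' opening and closing angular speeds, and the energy-expenditure proxy
#' IAV. Velocities and excursions are evaluated on the unfiltered
#' angular-velocity channel within the detected cycle windows (integration
#' itself smooths noise, and the zero-velocity update removes bias), with
#' the opening phase \code{[t_start, t_peak]} and closing phase
#' \code{[t_peak, t_end]}.
#'
#' @param cycles Cycle table from \code{\link{segment_taps}} on the same
#'   trial (times absolute).
#' @param r The \code{trial_recording}.
#' @param still_s Leading still-phase duration (s).
#' @return Named list: \code{tap}, \code{exc}, \code{exc_sd}, \code{wo},
#'   \code{wo_sd}, \code{wc}, \code{wc_sd}, \code{iav}. With no cycles,
#'   \code{tap} is 0 and the rest are \code{NA}; with a single cycle the
#'   SD fields are \code{NA}.
#' @export
extract_tapping_features <- function(cycles, r, still_s = 3) {
  stopifnot(inherits(r, "trial_recording"))
  fs <- r$fs
  feats <- setNames(as.list(rep(NA_real_, 8)), feature_names("FTAP"))
  feats$tap <- nrow(cycles)
  acc_parts <- trim_still_phase(r$acc, fs, still_s)
  baseline <- if (nrow(acc_parts$still) > 0) colMeans(acc_parts$still) else c(0, 0, 0)
  feats$iav <- iav(acc_parts$movement, fs, baseline)
  if (nrow(cycles) == 0) return(feats)
  g <- select_channel(r)
  t <- r$t
  idx_of <- function(tt) pmin(length(t), pmax(1, round(tt * fs) + 1))
  excs <- wos <- wcs <- numeric(nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    i1 <- idx_of(cycles$t_start[i])
    ip <- idx_of(cycles$t_peak[i])
    i3 <- idx_of(cycles$t_end[i])
    excs[i] <- angular_excursion(g[i1:i3], fs, drift_correct = TRUE)
    wos[i] <- max(abs(g[i1:ip]))
    wcs[i] <- max(abs(g[ip:i3]))
  }
  feats$exc <- mean(excs)
  feats$wo <- mean(wos)
  feats$wc <- mean(wcs)
  if (nrow(cycles) >= 2) {
    feats$exc_sd <- stats::sd(excs)
    feats$wo_sd <- stats::sd(wos)
    feats$wc_sd <- stats::sd(wcs)
  }
  feats
}

#' Kinematic features of one GAIT trial
#'
#' Computes the thirteen gait parameters from the detected gait cycles:
#' total gait time (first movement onset to last foot-flat), stride count,
#' velocity and stride length over the walked distance, stride/swing/
#' stance times with SDs (stride time is the interval between successive
#' movement onsets; swing is toe-off to heel strike; stance is the
#' remainder of the stride), relative stance, and the per-stride
#' drift-corrected swing angular excursion.
#'
#' @param cycles Cycle table from \code{\link{segment_gait}}.
#' @param r The \code{trial_recording}.
#' @param distance_m Walked distance (m), 10 by default.
#' @return Named list of the 13 gait features; fewer than 2 cycles gives
#'   all-\code{NA} with a warning.
#' @export
extract_gait_features <- function(cycles, r, distance_m = 10) {
  stopifnot(inherits(r, "trial_recording"))
  feats <- setNames(as.list(rep(NA_real_, 13)), feature_names("GAIT"))
  if (nrow(cycles) < 2) {
    warning("fewer than 2 gait cycles; gait features are missing")
    return(feats)
  }
  fs <- r$fs
  g <- select_channel(r)$gyro_y
  nC <- nrow(cycles)
  feats$gt <- cycles$t_flat[nC] - cycles$t_move[1]
  feats$gstrd <- nC
  feats$gvel <- distance_m / feats$gt
  feats$gstrd_l <- distance_m / nC
  stride_t <- diff(cycles$t_move)                      # n-1 full strides
  swing_t <- (cycles$t_heel_strike - cycles$t_toe_off)[seq_len(nC - 1)]
  stance_t <- stride_t - swing_t
  feats$gstrd_t <- mean(stride_t)
  feats$gstrd_t_sd <- sd0(stride_t)
  feats$gswt <- mean(swing_t)
  feats$gswt_sd <- sd0(swing_t)
  feats$gstt <- mean(stance_t)
  feats$gstt_sd <- sd0(stance_t)
  feats$grs <- mean(stance_t / stride_t)
  idx_of <- function(tt) pmin(length(g), pmax(1, round(tt * fs) + 1))
  gexc <- vapply(seq_len(nC), function(i) {
    seg <- g[idx_of(cycles$t_move[i]):idx_of(cycles$t_flat[i])]
    angular_excursion(seg, fs, drift_correct = TRUE)
  }, numeric(1))
  feats$gexc <- mean(gexc)
  feats$gexc_sd <- sd0(gexc)
  feats
}

#' Run detection and feature extraction on one trial
#'
#' Convenience wrapper: channel selection, still-phase trimming, low-pass
#' filtering, segmentation and feature extraction appropriate to the
#' trial's exercise.
#'
#' @param r A \code{trial_recording}.
#' @param tap_params,gait_params Detector settings.
#' @param still_s Leading still-phase duration (s).
#' @param distance_m Walked distance for GAIT (m).
#' @return Named list of features (8 for tapping, 13 for GAIT).
#' @export
process_trial <- function(r, tap_params = tap_detector_params(),
                          gait_params = gait_detector_params(),
                          still_s = 3, distance_m = 10) {
  stopifnot(inherits(r, "trial_recording"))
  if (r$exercise == "GAIT") {
    cycles <- segment_gait(r, gait_params, still_s = still_s)
    extract_gait_features(cycles, r, distance_m = distance_m)
  } else {
    parts <- trim_still_phase(select_channel(r), r$fs, still_s)
    noise_sd <- if (length(parts$still) > 1) stats::sd(parts$still) else 0
    cycles <- segment_taps(parts$movement, r$fs, tap_params,
                           noise_sd = noise_sd, t0 = still_s)
    extract_tapping_features(cycles, r, still_s = still_s)
  }
}

#' Assemble the per-cohort feature table
#'
#' Collects per-trial feature lists into the tidy feature table
#' f_i(Ex, CL_k, s_j). A complete 5-exercise, 4-load protocol yields 45
#' features per load and 180 feature columns in the wide layout.
#'
#' @param records A list where each element has \code{participant_id},
#'   \code{exercise}, \code{cl} and \code{features} (named list).
#' @return Tidy data.frame: \code{participant_id}, \code{exercise},
#'   \code{cl}, \code{feature}, \code{value}. Duplicate
#'   (participant, exercise, CL) cells are an error; missing trials are
#'   simply absent rows, never silent zeros.
#' @seealso \code{\link{feature_table_wide}}
#' @export
build_feature_table <- function(records) {
  if (length(records) == 0) {
    return(data.frame(participant_id = character(), exercise = character(),
                      cl = character(), feature = character(),
                      value = numeric()))
  }
  keys <- vapply(records, function(rec) {
    paste(rec$participant_id, rec$exercise, rec$cl, sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (participant, exercise, CL) trials: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "), call. = FALSE)
  }
  rows <- lapply(records, function(rec) {
    fn <- feature_names(rec$exercise)
    data.frame(participant_id = rec$participant_id, exercise = rec$exercise,
               cl = rec$cl, feature = fn,
               value = as.numeric(unlist(rec$features[fn])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Wide layout of a feature table
#'
#' One row per participant, one column per (exercise, feature, CL) cell,
#' named \code{<exercise>.<feature>.<CL>}.
#'
#' @param ft Tidy feature table from \code{\link{build_feature_table}}.
#' @return Wide data.frame with a \code{participant_id} column.
#' @export
feature_table_wide <- function(ft) {
  ids <- unique(ft$participant_id)
  cols <- unique(paste(ft$exercise, ft$feature, ft$cl, sep = "."))
  wide <- as.data.frame(matrix(NA_real_, nrow = length(ids),
                               ncol = length(cols),
                               dimnames = list(NULL, cols)))
  key <- paste(ft$exercise, ft$feature, ft$cl, sep = ".")
  for (r in seq_len(nrow(ft))) {
    wide[match(ft$participant_id[r], ids), key[r]] <- ft$value[r]
  }
  cbind(data.frame(participant_id = ids, stringsAsFactors = FALSE), wide)
}
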