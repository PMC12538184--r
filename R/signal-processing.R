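#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order (by default) low-pass Butterworth applied forward and
#' backward, so events are not lag-shifted. Coefficients come from
#' \code{signal::butter}; the forward-backward pass uses odd-reflection
#' end padding and a DC steady-state start (the output of a constant input
#' is that constant everywhere), which plain \code{signal::filtfilt}
#' does not guarantee at the edges.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param fc Cutoff frequency (Hz); must be below the Nyquist rate.
#' @param order Filter order of each pass (default 4).
#' @return Filtered signal, same length as \code{x}. Note the two-pass
#'   design squares the single-pass magnitude response.
#' @examples
#' x <- sin(2 * pi * 20 * (0:299) / 100) # 20 Hz tone at 100 Hz sampling
#' y <- butterworth_lowpass(x, fs = 100, fc = 5)
#' max(abs(y[100:200])) # strongly attenuated
#' @export
butterworth_lowpass <- function(x, fs, fc, order = 4) {
  if (fc >= fs / 2) stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  if (fc <= 0) stop("cutoff must be positive", call. = FALSE)
  n <- length(x)
  if (n <= 3 * order) stop("signal too short for the filter order", call. = FALSE)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  p <- min(n - 1, 9 * order)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  one_pass <- function(z) {
    # subtracting the first sample and adding it back afterwards places the
    # filter in its DC steady state (unit DC gain), removing the step
    # transient; the odd reflection handles the residual slope
    z[1] + as.numeric(signal::filter(bf, z - z[1]))
  }
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[(p + 1):(p + n)]
}

#' Select the informative channel(s) of a trial
#'
#' For the tapping exercises the analysis uses the angular velocity
#' orthogonal to the movement plane (gyroscope y). GAIT is analysed in the
#' sagittal plane, bundling the x and z accelerations with gyroscope y.
#'
#' @param r A \code{trial_recording}.
#' @return For tapping, the gyro-y channel (numeric vector). For GAIT, a
#'   list with \code{acc_x}, \code{acc_z} and \code{gyro_y}.
#' @export
select_channel <- function(r) {
  stopifnot(inherits(r, "trial_recording"))
  assert_choice(r$exercise, mcdt_exercises(), "exercise")
  need <- function(m, ch, what) {
    if (!ch %in% colnames(m)) {
      stop(sprintf("recording is missing the %s-%s channel", what, ch),
           call. = FALSE)
    }
    m[, ch]
  }
  if (r$exercise == "GAIT") {
    list(acc_x = need(r$acc, "x", "acc"),
         acc_z = need(r$acc, "z", "acc"),
         gyro_y = need(r$gyro, "y", "gyro"))
  } else {
    need(r$gyro, "y", "gyro")
  }
}

#' Split a trial into still and movement windows
#'
#' Every trial begins with a still phase used for noise and gravity
#' estimation; the remainder is the movement window.
#'
#' @param x Numeric channel (or matrix with one channel per column).
#' @param fs Sampling rate (Hz).
#' @param still_s Still-phase duration in seconds (default 3).
#' @return A list with \code{movement} and \code{still} (same type as
#'   \code{x}).
#' @examples
#' parts <- trim_still_phase(rnorm(1800), fs = 100, still_s = 3)
#' length(parts$movement) # 1500
#' @export
trim_still_phase <- function(x, fs, still_s = 3) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  n_still <- round(still_s * fs)
  if (n <= n_still) stop("trial shorter than the still phase", call. = FALSE)
  take <- function(idx) if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  if (n_still == 0) return(list(movement = x, still = take(integer(0))))
  list(movement = take((n_still + 1):n), still = take(seq_len(n_still)))
}

#' Detector settings for tapping segmentation
#'
#' @param floor_dps Fixed amplitude-threshold floor (degrees/s).
#' @param k_noise Multiplier on the still-phase noise SD.
#' @param peak_frac Fraction of the trial's 98th-percentile |amplitude|
#'   that an opening peak / closing trough must reach. Band-limiting a
#'   tap train to the preprocessing cutoff creates rebound oscillations
#'   between taps of roughly 15-20 percent of the lobe peaks; requiring
#'   extrema above ~a third of the trial's amplitude scale rejects them
#'   while keeping even strongly jittered genuine taps.
#' @param edge_frac Like \code{peak_frac} but for the lower edge
#'   threshold at which cycle onset/offset crossings are placed.
#' @param min_period_s Minimum spacing between opening peaks (s); closer
#'   candidates are treated as one tap, keeping the larger.
#' @param refine_s Half-width of the window in which the peak time is
#'   refined on the unfiltered signal (s).
#' @param fc Low-pass cutoff used for detection (Hz).
#' @return A list of settings.
#' @export
tap_detector_params <- function(floor_dps = 10, k_noise = 5,
                                peak_frac = 0.35, edge_frac = 0.10,
                                min_period_s = 0.15,
                                refine_s = 0.03, fc = 5) {
  list(floor_dps = floor_dps, k_noise = k_noise, peak_frac = peak_frac,
       edge_frac = edge_frac, min_period_s = min_period_s,
       refine_s = refine_s, fc = fc)
}

# local maxima (or minima) of x beyond a signed threshold, with a minimum
# spacing; of two close candidates the more extreme wins
signed_peaks <- function(x, thr, min_gap, maximum = TRUE) {
  s <- if (maximum) x else -x
  cand <- which(c(FALSE, diff(sign(diff(s))) < 0, FALSE) & s > thr)
  peaks <- integer(0)
  for (j in cand) {
    if (length(peaks) == 0 || j - peaks[length(peaks)] >= min_gap) {
      peaks <- c(peaks, j)
    } else if (s[j] > s[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- j
    }
  }
  peaks
}

# linearly interpolated downward zero-crossing time (in samples, 1-based)
# between j and j+1
interp_crossing <- function(x, j) {
  j + x[j] / (x[j] - x[j + 1])
}

#' Segment a tapping trial into movement cycles
#'
#' Detects tap cycles on the zero-phase-filtered angular velocity. Each
#' cycle is an opening peak (local maximum above the working threshold)
#' paired with the first closing trough (local minimum below its negative)
#' that follows it before the next opening peak. The three characteristic
#' times are the onset (\code{t_start}, where the rising edge last crossed
#' the threshold), the opening-to-closing transition, i.e. the zero
#' crossing between the lobes (\code{t_peak}, refined on the unfiltered
#' signal), and the offset (\code{t_end}, where the closing lobe re-rises
#' through the negative threshold). Partial cycles touching the window
#' edges are discarded.
#'
#' @param omega_y Angular velocity channel, movement window only
#'   (degrees/s), unfiltered.
#' @param fs Sampling rate (Hz).
#' @param params \code{\link{tap_detector_params}}.
#' @param noise_sd Still-phase noise SD estimate (degrees/s); 0 if unknown.
#' @param t0 Time of the first sample (s); detected times are absolute
#'   under this offset.
#' @return data.frame with \code{cycle}, \code{t_start}, \code{t_peak},
#'   \code{t_end} (seconds); zero rows when nothing is detected.
#' @export
segment_taps <- function(omega_y, fs, params = tap_detector_params(),
                         noise_sd = 0, t0 = 0) {
  xf <- butterworth_lowpass(omega_y, fs, params$fc)
  q98 <- stats::quantile(abs(xf), 0.98)
  base_thr <- max(params$floor_dps, params$k_noise * noise_sd)
  thr <- max(base_thr, params$peak_frac * q98)
  thr_edge <- max(base_thr, params$edge_frac * q98)
  empty <- data.frame(cycle = integer(), t_start = numeric(),
                      t_peak = numeric(), t_end = numeric())
  n <- length(xf)
  min_gap <- round(params$min_period_s * fs)
  peaks <- signed_peaks(xf, thr, min_gap, maximum = TRUE)
  troughs <- signed_peaks(xf, thr, min_gap, maximum = FALSE)
  if (length(peaks) == 0 || length(troughs) == 0) return(empty)
  refine_n <- round(params$refine_s * fs)
  out <- empty
  for (i in seq_along(peaks)) {
    pk <- peaks[i]
    nxt <- if (i < length(peaks)) peaks[i + 1] else n + 1L
    tr <- troughs[troughs > pk & troughs < nxt]
    if (length(tr) == 0) next # opening without a closing lobe
    tr <- tr[1]
    prev_tr <- troughs[troughs < pk]
    lo_bound <- if (length(prev_tr)) prev_tr[length(prev_tr)] else 1L
    # onset: rising edge's last crossing below the edge threshold
    s <- pk
    while (s > lo_bound && xf[s] > thr_edge) s <- s - 1
    # offset: closing lobe re-rising through the negative edge threshold
    e <- tr
    while (e < n && xf[e] < -thr_edge) e <- e + 1
    if (s <= 1 || e >= n) next # partial cycle at a window edge
    # zero crossing between the lobes, on the filtered signal first
    j <- pk
    while (j < tr && !(xf[j] >= 0 && xf[j + 1] < 0)) j <- j + 1
    if (j >= tr) next
    # refine on the raw signal in a small window around the candidate
    lo <- max(pk, j - refine_n)
    hi <- min(tr - 1, j + refine_n)
    jr <- NA_integer_
    for (m in lo:hi) {
      if (omega_y[m] >= 0 && omega_y[m + 1] < 0) { jr <- m; break }
    }
    cross <- if (is.na(jr)) interp_crossing(xf, j) else interp_crossing(omega_y, jr)
    out <- rbind(out, data.frame(
      cycle = nrow(out) + 1L,
      t_start = t0 + (s - 1) / fs,
      t_peak = t0 + (cross - 1) / fs,
      t_end = t0 + (e - 1) / fs))
  }
  out$cycle <- seq_len(nrow(out))
  out
}

#' Detector settings for gait segmentation
#'
#' @param peak_floor_dps Minimum mid-swing peak amplitude (degrees/s).
#' @param event_floor_dps Minimum |amplitude| for the toe-off/heel-strike
#'   minima (degrees/s).
#' @param flat_floor_dps Quiet-threshold floor for foot-flat detection
#'   (degrees/s).
#' @param k_noise Multiplier on the still-phase noise SD for the quiet
#'   threshold.
#' @param min_stride_s Minimum spacing between mid-swing peaks (s).
#' @param search_s Search window before/after mid-swing for the flanking
#'   minima (s).
#' @param quiet_s Duration the signal must stay quiet to declare foot-flat
#'   or movement onset (s).
#' @param refine_s Extremum refinement half-window on the raw signal (s).
#' @param fc Low-pass cutoff used for detection (Hz).
#' @return A list of settings.
#' @export
gait_detector_params <- function(peak_floor_dps = 40, event_floor_dps = 15,
                                 flat_floor_dps = 3, k_noise = 3,
                                 min_stride_s = 0.6, search_s = 0.6,
                                 quiet_s = 0.05, refine_s = 0.03, fc = 3) {
  list(peak_floor_dps = peak_floor_dps, event_floor_dps = event_floor_dps,
       flat_floor_dps = flat_floor_dps, k_noise = k_noise,
       min_stride_s = min_stride_s, search_s = search_s, quiet_s = quiet_s,
       refine_s = refine_s, fc = fc)
}

# local extremum refinement on the raw signal around index j
refine_extremum <- function(raw, j, w, maximum) {
  lo <- max(1, j - w); hi <- min(length(raw), j + w)
  win <- raw[lo:hi]
  lo - 1 + if (maximum) which.max(win) else which.min(win)
}

#' Segment a GAIT trial into gait cycles
#'
#' Standard foot/shank gyroscope event logic on the sagittal angular
#' velocity: mid-swing is a prominent positive peak; toe-off is the last
#' negative minimum before it and heel strike the first negative minimum
#' after it; movement onset (\code{t_move}) is where the signal last left
#' the quiet band before toe-off, and foot-flat (\code{t_flat}) where it
#' re-enters and stays in the quiet band after heel strike. Candidates are
#' found on the zero-phase 3 Hz-filtered signal and each extremum is then
#' refined on the unfiltered signal.
#'
#' @param r A \code{trial_recording} of the GAIT exercise.
#' @param params \code{\link{gait_detector_params}}.
#' @param still_s Leading still-phase duration (s) used for noise
#'   estimation.
#' @return data.frame with \code{cycle}, \code{t_move}, \code{t_toe_off},
#'   \code{t_heel_strike}, \code{t_flat} in absolute trial seconds. Fewer
#'   than 2 detected strides returns an empty result with a warning.
#' @export
segment_gait <- function(r, params = gait_detector_params(), still_s = 3) {
  stopifnot(inherits(r, "trial_recording"))
  if (r$exercise != "GAIT") stop("segment_gait expects a GAIT trial", call. = FALSE)
  fs <- r$fs
  parts <- trim_still_phase(select_channel(r)$gyro_y, fs, still_s)
  raw <- parts$movement
  noise_sd <- if (length(parts$still) > 1) stats::sd(parts$still) else 0
  xf <- butterworth_lowpass(raw, fs, params$fc)
  quiet_thr <- max(params$flat_floor_dps, params$k_noise * noise_sd)
  empty <- data.frame(cycle = integer(), t_move = numeric(),
                      t_toe_off = numeric(), t_heel_strike = numeric(),
                      t_flat = numeric())
  # mid-swing candidates: local maxima above threshold, one per stride
  min_gap <- round(params$min_stride_s * fs)
  n <- length(xf)
  is_peak <- c(FALSE, diff(sign(diff(xf))) < 0, FALSE) &
    xf > params$peak_floor_dps
  cand <- which(is_peak)
  peaks <- integer(0)
  for (j in cand) {
    if (length(peaks) == 0 || j - peaks[length(peaks)] >= min_gap) {
      peaks <- c(peaks, j)
    } else if (xf[j] > xf[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- j
    }
  }
  w_ref <- round(params$refine_s * fs)
  w_search <- round(params$search_s * fs)
  quiet_n <- max(1, round(params$quiet_s * fs))
  quiet <- abs(raw) < quiet_thr
  cycles <- empty
  for (pk in peaks) {
    pk_r <- refine_extremum(raw, pk, w_ref, maximum = TRUE)
    # toe-off: last negative local minimum before mid-swing
    lo <- max(2, pk - w_search)
    pre <- xf[lo:pk]
    mins <- which(diff(sign(diff(pre))) > 0) + 1
    mins <- mins[pre[mins] < -params$event_floor_dps]
    if (length(mins) == 0) next
    i_to <- refine_extremum(raw, lo - 1 + mins[length(mins)], w_ref, maximum = FALSE)
    # heel strike: first negative local minimum after mid-swing
    hi <- min(n - 1, pk + w_search)
    post <- xf[pk:hi]
    mins2 <- which(diff(sign(diff(post))) > 0) + 1
    mins2 <- mins2[post[mins2] < -params$event_floor_dps]
    if (length(mins2) == 0) next
    i_hs <- refine_extremum(raw, pk - 1 + mins2[1], w_ref, maximum = FALSE)
    # movement onset: walk back from toe-off to the end of the last quiet run
    i_mv <- NA_integer_
    j <- i_to
    while (j > quiet_n) {
      if (sum(quiet[(j - quiet_n + 1):j]) >= quiet_n - 1) { i_mv <- j; break }
      j <- j - 1
    }
    if (is.na(i_mv)) i_mv <- max(1, i_to - w_search)
    # foot flat: first sustained quiet run after heel strike
    i_fl <- NA_integer_
    j <- i_hs
    while (j + quiet_n - 1 <= length(quiet)) {
      if (sum(quiet[j:(j + quiet_n - 1)]) >= quiet_n - 1) { i_fl <- j; break }
      j <- j + 1
    }
    if (is.na(i_fl)) next
    if (!(i_mv < i_to && i_to < pk_r && pk_r < i_hs && i_hs < i_fl)) next
    cycles <- rbind(cycles, data.frame(
      cycle = nrow(cycles) + 1L,
      t_move = still_s + (i_mv - 1) / fs,
      t_toe_off = still_s + (i_to - 1) / fs,
      t_heel_strike = still_s + (i_hs - 1) / fs,
      t_flat = still_s + (i_fl - 1) / fs))
  }
  # enforce strictly increasing, non-overlapping cycles
  if (nrow(cycles) > 1) {
    keep <- c(TRUE, diff(cycles$t_move) > 0 &
                cycles$t_move[-1] >= cycles$t_flat[-nrow(cycles)])
    cycles <- cycles[keep, , drop = FALSE]
    cycles$cycle <- seq_len(nrow(cycles))
  }
  if (nrow(cycles) < 2) {
    warning("fewer than 2 gait strides detected; returning empty result")
    return(empty)
  }
  cycles
}
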