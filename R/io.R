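# Trial and participant CSV dialects.
#
# Trial files: columns time_s, acc_x, acc_y, acc_z (m/s^2), gyro_x, gyro_y,
# gyro_z (degrees/s); mandatory header; one file per (participant, exercise,
# CL) named <participant>_<exercise>_<CL>.csv.

trial_columns <- function() {
  c("time_s", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
}

#' Canonical trial filename
#'
#' @param participant_id,exercise,cl Trial identity.
#' @return \code{"<participant>_<exercise>_<CL>.csv"}.
#' @export
trial_filename <- function(participant_id, exercise, cl) {
  sprintf("%s_%s_%s.csv", participant_id, exercise, cl)
}

#' Write a trial recording to CSV
#'
#' @param r A \code{trial_recording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial <- function(r, path) {
  stopifnot(inherits(r, "trial_recording"))
  df <- data.frame(time_s = r$t,
                   acc_x = r$acc[, "x"], acc_y = r$acc[, "y"],
                   acc_z = r$acc[, "z"],
                   gyro_x = r$gyro[, "x"], gyro_y = r$gyro[, "y"],
                   gyro_z = r$gyro[, "z"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial recording from CSV
#'
#' Validates the column dialect and time-base uniformity (to 1e-6 s) and
#' infers the sampling rate from the median sample interval. The trial
#' identity is parsed from the filename when it follows the
#' \code{<participant>_<exercise>_<CL>.csv} pattern, or can be given
#' explicitly.
#'
#' @param path CSV file path.
#' @param participant_id,exercise,cl Optional identity overrides.
#' @return A \code{trial_recording}.
#' @export
read_trial <- function(path, participant_id = NULL, exercise = NULL,
                       cl = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(trial_columns(), names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: malformed header, missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  t <- df$time_s
  if (length(t) < 2) stop(path, ": too few samples", call. = FALSE)
  dts <- diff(t)
  if (any(dts <= 0)) {
    stop(sprintf("%s: non-monotone time at line %d", path,
                 which(dts <= 0)[1] + 1L), call. = FALSE)
  }
  dt <- stats::median(dts)
  off <- which(abs(dts - dt) > 1e-6)
  if (length(off)) {
    stop(sprintf("%s: non-uniform sampling at line %d", path, off[1] + 1L),
         call. = FALSE)
  }
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  if (is.null(participant_id)) {
    participant_id <- if (length(parts) >= 3)
      paste(parts[seq_len(length(parts) - 2)], collapse = "_") else base
  }
  if (is.null(exercise)) {
    exercise <- if (length(parts) >= 3) parts[length(parts) - 1] else NA
  }
  if (is.null(cl)) cl <- if (length(parts) >= 3) parts[length(parts)] else NA
  new_trial_recording(
    participant_id, exercise, cl, fs = 1 / dt, t = t,
    acc = as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
    gyro = as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")]))
}

#' Write / read a participant table
#'
#' @param participants Participant table.
#' @param path CSV file path.
#' @return The path (write) or the parsed table with factor columns
#'   restored (read).
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "sex", "education", "fab", "mmse")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$group <- factor(df$group, levels = mcdt_groups())
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df$education <- factor(df$education,
                         levels = c("primary", "secondary", "superior"))
  df
}
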