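#' Dual-task cost
#'
#' Percent change of a feature under dual task relative to its single-task
#' baseline: \code{100 * (f_dt - f_st) / f_st}. A zero baseline makes the
#' cost undefined (returned as \code{NA} with a warning); negative
#' baselines are likewise treated as undefined by the table builder, since
#' the cost is scale-relative.
#'
#' @param f_dt Feature value under dual task (vectorized).
#' @param f_st Feature value at single-task baseline (CL0).
#' @return Cost in percent; \code{NA} where the baseline is 0 or missing.
#' @examples
#' dtc(5, 10)  # -50
#' dtc(10, 10) # 0
#' @export
dtc <- function(f_dt, f_st) {
  out <- 100 * (f_dt - f_st) / f_st
  zero <- !is.na(f_st) & f_st == 0
  if (any(zero)) {
    warning(sum(zero), " zero single-task baseline(s); cost set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Affine rescale to a bounded interval
#'
#' Order-preserving affine map sending the sample minimum to \code{a} and
#' the maximum to \code{b}. When all values are equal there is no spread
#' to map, and every value is sent to \code{b} (no down-weighting without
#' evidence).
#'
#' @param x Numeric vector.
#' @param a,b Target bounds, \code{0 < a < b}; defaults 0.01 and 1 (the
#'   lower bound avoids exact-zero weights).
#' @return Rescaled vector within \code{[a, b]}.
#' @examples
#' rescale_unit(c(0, 5, 10)) # 0.01 0.505 1
#' @export
rescale_unit <- function(x, a = 0.01, b = 1) {
  stopifnot(length(x) >= 1, a > 0, a < b)
  fin <- is.finite(x)
  if (!any(fin)) return(rep(NA_real_, length(x)))
  lo <- min(x[fin]); hi <- max(x[fin])
  if (hi == lo) {
    out <- rep(b, length(x))
    out[!fin] <- NA_real_
    return(out)
  }
  out <- a + (x - lo) / (hi - lo) * (b - a)
  out[!fin] <- NA_real_
  out
}

#' Cognitive weights from correct-response counts
#'
#' Standardizes the correct-response counts Nc across participants
#' (z-score) and rescales the result into [0.01, 1]. Because both steps
#' are affine, the composition equals a direct min-max rescale of the raw
#' counts; the z-scoring is retained to mirror the standardization on the
#' analyzed sample. Degenerate spreads (a single participant, or all
#' counts equal) carry no evidence of differential commitment and map to
#' weight 1 with a warning, reproducing the unweighted cost.
#'
#' @param nc Integer vector of correct responses for one (exercise, CL)
#'   slice, one entry per participant.
#' @param a,b Rescale bounds (see \code{\link{rescale_unit}}).
#' @return Weight vector Zc in \code{[a, b]}, monotone in \code{nc}.
#' @examples
#' zc_scores(c(0, 5, 10)) # 0.01 0.505 1
#' @export
zc_scores <- function(nc, a = 0.01, b = 1) {
  stopifnot(length(nc) >= 1)
  if (any(nc < 0, na.rm = TRUE)) stop("nc must be >= 0", call. = FALSE)
  fin <- is.finite(nc)
  s <- stats::sd(nc[fin])
  if (sum(fin) < 2 || is.na(s) || s == 0) {
    warning("degenerate Nc spread; all weights set to 1")
    out <- rep(1, length(nc))
    out[!fin] <- NA_real_
    return(out)
  }
  z <- (nc - mean(nc[fin])) / s
  rescale_unit(z, a, b)
}

#' Cognitively weighted feature value
#'
#' Product of a dual-task feature value and its cognitive weight Zc. Only
#' defined under dual task (k > 0): there is no counting at baseline.
#'
#' @param f Feature value(s).
#' @param zc Weight(s) in [0.01, 1].
#' @param cl Optional load label; \code{"CL0"} is an error.
#' @return \code{f * zc}.
#' @export
weighted_feature <- function(f, zc, cl = NULL) {
  if (!is.null(cl) && any(cl == "CL0")) {
    stop("weighted features are possible only where k>0 (not at baseline)",
         call. = FALSE)
  }
  f * zc
}

#' Cognitive score table with weights
#'
#' Attaches the Zc weight to each (participant, exercise, CL) count,
#' standardizing across the whole analyzed sample within each
#' (exercise, CL) slice (all diagnostic groups pooled).
#'
#' @param responses data.frame with \code{participant_id},
#'   \code{exercise}, \code{cl} (CL1-CL3) and \code{nc}.
#' @param a,b Rescale bounds.
#' @return The input with a \code{zc} column.
#' @export
cognitive_score_table <- function(responses, a = 0.01, b = 1) {
  stopifnot(all(c("participant_id", "exercise", "cl", "nc") %in%
                  names(responses)))
  if (any(responses$cl == "CL0")) {
    stop("responses are defined only for CL1-CL3", call. = FALSE)
  }
  responses$zc <- NA_real_
  for (ex in unique(responses$exercise)) {
    for (cl in unique(responses$cl)) {
      sel <- responses$exercise == ex & responses$cl == cl
      if (!any(sel)) next
      responses$zc[sel] <- zc_scores(responses$nc[sel], a, b)
    }
  }
  responses
}

#' Standard and weighted dual-task cost table
#'
#' For every feature, exercise and dual-task load, computes the standard
#' cost \code{DTC = 100 (f_k - f_0) / f_0} and the weighted cost
#' \code{DTC* = 100 (f_k * Zc - f_0) / f_0}, where Zc is the participant's
#' rescaled correct-response weight for that (exercise, load). The weight
#' is shared by all features of the exercise. Cells whose baseline is
#' missing, zero or negative are \code{NA} (with one summary warning).
#'
#' @param features Tidy feature table (\code{\link{build_feature_table}}).
#' @param responses Response counts (see
#'   \code{\link{cognitive_score_table}}); may already contain \code{zc}.
#' @return Tidy data.frame: \code{participant_id}, \code{exercise},
#'   \code{cl} (CL1-CL3), \code{feature}, \code{f}, \code{f0}, \code{zc},
#'   \code{dtc}, \code{dtc_star}.
#' @export
weighted_dtc_table <- function(features, responses) {
  if (!"zc" %in% names(responses)) {
    responses <- cognitive_score_table(responses)
  }
  base <- features[features$cl == "CL0", ]
  dt <- features[features$cl != "CL0", ]
  key <- function(d) paste(d$participant_id, d$exercise, d$feature, sep = "|")
  f0 <- base$value[match(key(dt), key(base))]
  rkey <- function(d) paste(d$participant_id, d$exercise, d$cl, sep = "|")
  zc <- responses$zc[match(rkey(dt), rkey(responses))]
  bad <- is.na(f0) | f0 <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with missing or non-positive baseline; ",
            "costs set to NA")
  }
  denom <- ifelse(bad, NA_real_, f0)
  out <- data.frame(participant_id = dt$participant_id,
                    exercise = dt$exercise, cl = dt$cl,
                    feature = dt$feature, f = dt$value, f0 = f0, zc = zc,
                    dtc = 100 * (dt$value - denom) / denom,
                    dtc_star = 100 * (dt$value * zc - denom) / denom,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
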