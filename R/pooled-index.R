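#' Screening configuration for pooled-index construction
#'
#' @param rho_threshold Spearman |rho| at or above which two candidate
#'   columns are considered redundant (default 0.4).
#' @param max_components Maximum number of components per pooled index
#'   (default 6).
#' @param orientation_map Named vector of +1/-1 per base feature name:
#'   +1 when a higher raw value indicates better functioning, -1 when
#'   lower is better (see \code{\link{default_orientation_map}}).
#' @param priority_list Ordered character vector of column names used as
#'   the final theoretical tie-break: earlier entries are kept in
#'   preference to later or unlisted ones.
#' @return A list of class \code{"screening_config"}.
#' @export
screening_config <- function(rho_threshold = 0.4, max_components = 6,
                             orientation_map = default_orientation_map(),
                             priority_list = character()) {
  stopifnot(rho_threshold > 0, rho_threshold < 1, max_components >= 1)
  structure(list(rho_threshold = rho_threshold,
                 max_components = max_components,
                 orientation_map = orientation_map,
                 priority_list = priority_list),
            class = "screening_config")
}

#' Default feature orientations
#'
#' Sign per kinematic parameter so that, after multiplication, higher
#' oriented values indicate better functioning: counts, excursions and
#' velocities are higher-better (+1); every variability (SD) feature, the
#' time features, stride count, relative stance and the energy proxy are
#' lower-better (-1). The mapping is a package default and can be
#' overridden in \code{\link{screening_config}}.
#'
#' @return Named numeric vector of +1/-1 over all 21 base feature names.
#' @export
default_orientation_map <- function() {
  c(tap = 1, exc = 1, exc_sd = -1, wo = 1, wo_sd = -1, wc = 1, wc_sd = -1,
    iav = -1,
    gt = -1, gstrd = -1, gvel = 1, gstrd_l = 1, gstrd_t = -1,
    gstrd_t_sd = -1, gswt = -1, gswt_sd = -1, gstt = -1, gstt_sd = -1,
    grs = -1, gexc = 1, gexc_sd = -1)
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlations among candidate DTC* columns, with pairwise deletion
#' of missing cells. Columns with fewer than 3 non-missing values are
#' excluded with a warning.
#'
#' @param columns data.frame or matrix, one candidate column per variable.
#' @return Symmetric correlation matrix with unit diagonal over the
#'   retained columns.
#' @export
spearman_matrix <- function(columns) {
  x <- as.matrix(columns)
  if (ncol(x) < 2) stop("need at least 2 columns", call. = FALSE)
  n_ok <- colSums(!is.na(x))
  if (any(n_ok < 3)) {
    warning("excluding column(s) with < 3 non-missing values: ",
            paste(colnames(x)[n_ok < 3], collapse = ", "))
    x <- x[, n_ok >= 3, drop = FALSE]
  }
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  rho
}

#' Cohen's d between two groups
#'
#' Standardized mean difference with the pooled standard deviation
#' \code{sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2))}. The sign is
#' mean(A) - mean(B) over the first factor level minus the second.
#'
#' @param x Numeric values.
#' @param groups Two-level factor (or coercible) of the same length.
#' @return List with \code{d} and \code{contrast}.
#' @examples
#' cohens_d(c(1, 2, 3, 3, 4, 5), rep(c("A", "B"), each = 3)) # d = -2
#' @export
cohens_d <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels", call. = FALSE)
  keep <- !is.na(x) & !is.na(groups)
  x <- x[keep]; groups <- droplevels(groups[keep])
  a <- x[groups == levels(groups)[1]]
  b <- x[groups == levels(groups)[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 members", call. = FALSE)
  }
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  list(d = (mean(a) - mean(b)) / sp, contrast = levels(groups))
}

#' Iterative redundancy screening of DTC* columns
#'
#' Implements the deletion procedure used to build each pooled index.
#' Repeatedly: count, for every candidate column, its partners with
#' Spearman \code{|rho| >= rho_threshold}; delete the column with the most
#' such partners. Ties are broken by the lower absolute Cohen's d on the
#' MCI-vs-OA contrast, then by the configured priority list (columns
#' absent from the list, or later in it, are deleted first). Deletion
#' stops when no redundant pair remains; if more than
#' \code{max_components} mutually low-correlation columns survive, the
#' ones with the highest |d| are kept.
#'
#' @param columns data.frame of candidate columns (rows = participants).
#' @param labels Diagnosis factor (OA/SCI/MCI) aligned with the rows.
#' @param cfg A \code{\link{screening_config}}.
#' @return List of class \code{"mcdt_screening"}: \code{selected}
#'   (surviving column names), \code{trace} (data.frame of deletions with
#'   the rule that fired), \code{effect_sizes}.
#' @export
screen_features <- function(columns, labels, cfg = screening_config()) {
  x <- as.data.frame(columns)
  if (ncol(x) == 0) stop("empty candidate pool", call. = FALSE)
  labels <- factor(labels, levels = mcdt_groups())
  stopifnot(length(labels) == nrow(x))
  abs_d <- vapply(x, function(col) {
    sub <- labels %in% c("MCI", "OA")
    d <- tryCatch(cohens_d(col[sub], droplevels(labels[sub]))$d,
                  error = function(e) NA_real_)
    if (is.na(d)) 0 else abs(d)
  }, numeric(1))
  prio_rank <- function(nm) {
    r <- match(nm, cfg$priority_list)
    r[is.na(r)] <- length(cfg$priority_list) + match(nm, colnames(columns))[is.na(r)]
    r
  }
  trace <- data.frame(step = integer(), deleted = character(),
                      rule = character(), high_rho_count = integer(),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (ncol(x) == 1) break
    rho <- spearman_matrix(x)
    x <- x[, colnames(rho), drop = FALSE] # in case columns were excluded
    counts <- rowSums(abs(rho) >= cfg$rho_threshold & upper_or_lower(rho))
    if (max(counts) == 0) break
    cand <- names(counts)[counts == max(counts)]
    rule <- "max high-rho count"
    if (length(cand) > 1) {
      dmin <- abs_d[cand]
      cand <- cand[dmin == min(dmin)]
      rule <- "lower |Cohen d| (MCI vs OA)"
      if (length(cand) > 1) {
        cand <- cand[which.max(prio_rank(cand))]
        rule <- "priority list"
      }
    }
    victim <- cand[1]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, deleted = victim,
                                     rule = rule,
                                     high_rho_count = max(counts)))
    x <- x[, setdiff(colnames(x), victim), drop = FALSE]
  }
  selected <- colnames(x)
  if (length(selected) > cfg$max_components) {
    keep <- names(sort(abs_d[selected], decreasing = TRUE))[seq_len(cfg$max_components)]
    dropped <- setdiff(selected, keep)
    for (v in dropped) {
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, deleted = v,
                                       rule = "over max_components, lower |d|",
                                       high_rho_count = 0L))
    }
    selected <- keep
  }
  structure(list(selected = selected, trace = trace,
                 effect_sizes = abs_d),
            class = "mcdt_screening")
}

# off-diagonal mask
upper_or_lower <- function(m) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  diag(out) <- FALSE
  out
}

#' @export
print.mcdt_screening <- function(x, ...) {
  cat("<mcdt_screening>", length(x$selected), "component(s) selected:\n ",
      paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$trace)) {
    cat("deletion trace:\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}

#' Orient a column so that higher means better functioning
#'
#' @param x Numeric column of DTC* values for one feature.
#' @param feature Base feature name (e.g. \code{"tap"}); must be present
#'   in the orientation map -- there is no silent default.
#' @param map Orientation map (named +1/-1 vector).
#' @return \code{x} multiplied by its orientation sign.
#' @export
orient_higher_better <- function(x, feature,
                                 map = default_orientation_map()) {
  if (!feature %in% names(map)) {
    stop("feature '", feature, "' is missing from the orientation map",
         call. = FALSE)
  }
  x * map[[feature]]
}

#' Pooled composite score
#'
#' Each selected (already oriented) column is min-max normalized to [0, 1]
#' across participants and the normalized scores are averaged per
#' participant with a missing-aware mean.
#'
#' @param columns data.frame of selected oriented columns (rows =
#'   participants).
#' @param participant_id Optional identifier vector for the output.
#' @return data.frame with \code{participant_id} (if given) and
#'   \code{score} in [0, 1]; participants missing every component get
#'   \code{NA} with a warning.
#' @export
pooled_score <- function(columns, participant_id = NULL) {
  x <- as.data.frame(columns)
  if (ncol(x) < 1) stop("need at least 1 selected column", call. = FALSE)
  norm <- vapply(x, function(col) {
    fin <- is.finite(col)
    if (!any(fin)) return(rep(NA_real_, length(col)))
    lo <- min(col[fin]); hi <- max(col[fin])
    if (hi == lo) return(ifelse(fin, 1, NA_real_))
    out <- (col - lo) / (hi - lo)
    out[!fin] <- NA_real_
    out
  }, numeric(nrow(x)))
  norm <- matrix(norm, nrow = nrow(x))
  score <- rowMeans(norm, na.rm = TRUE)
  all_missing <- rowSums(!is.na(norm)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " participant(s) missing every component; ",
            "score set to NA")
    score[all_missing] <- NA_real_
  }
  if (is.null(participant_id)) data.frame(score = score)
  else data.frame(participant_id = participant_id, score = score,
                  stringsAsFactors = FALSE)
}

#' Build the pooled index for every exercise
#'
#' Runs orientation, screening and scoring on the DTC* columns of each
#' exercise. The candidate pool of an exercise spans its features across
#' all three dual-task loads (columns named \code{<feature>_<CL>}).
#'
#' @param dtc_table Output of \code{\link{weighted_dtc_table}}.
#' @param labels Named diagnosis vector or factor: either one entry per
#'   participant id present in \code{dtc_table} (named), or aligned with
#'   \code{sort(unique(participant_id))}.
#' @param cfg A \code{\link{screening_config}}.
#' @return List of class \code{"pooled_index_table"}: \code{scores}
#'   (data.frame \code{participant_id}, \code{exercise}, \code{score}) and
#'   \code{selection} (per-exercise \code{mcdt_screening} objects).
#' @export
build_pooled_indices <- function(dtc_table, labels,
                                 cfg = screening_config()) {
  ids <- sort(unique(dtc_table$participant_id))
  if (!is.null(names(labels))) labels <- labels[ids]
  labels <- factor(labels, levels = mcdt_groups())
  stopifnot(length(labels) == length(ids))
  scores <- list()
  selection <- list()
  for (ex in unique(dtc_table$exercise)) {
    d <- dtc_table[dtc_table$exercise == ex, ]
    pool <- as.data.frame(matrix(
      NA_real_, nrow = length(ids),
      ncol = length(unique(paste(d$feature, d$cl, sep = "_")))))
    colnames(pool) <- unique(paste(d$feature, d$cl, sep = "_"))
    for (r in seq_len(nrow(d))) {
      pool[match(d$participant_id[r], ids),
           paste(d$feature[r], d$cl[r], sep = "_")] <- d$dtc_star[r]
    }
    # orient before screening so the pooled average is well defined
    for (cn in colnames(pool)) {
      base <- sub("_CL[0-9]+$", "", cn)
      pool[[cn]] <- orient_higher_better(pool[[cn]], base,
                                         cfg$orientation_map)
    }
    scr <- screen_features(pool, labels, cfg)
    selection[[ex]] <- scr
    ps <- pooled_score(pool[, scr$selected, drop = FALSE],
                       participant_id = ids)
    ps$exercise <- ex
    scores[[ex]] <- ps[, c("participant_id", "exercise", "score")]
  }
  structure(list(scores = do.call(rbind, c(scores, make.row.names = FALSE)),
                 selection = selection),
            class = "pooled_index_table")
}

#' @export
print.pooled_index_table <- function(x, ...) {
  cat("<pooled_index_table>", length(unique(x$scores$exercise)),
      "exercise(s),", length(unique(x$scores$participant_id)),
      "participant(s)\n")
  for (ex in names(x$selection)) {
    cat(sprintf("  %s: %s\n", ex,
                paste(x$selection[[ex]]$selected, collapse = ", ")))
  }
  invisible(x)
}
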