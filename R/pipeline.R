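#' Pipeline run configuration
#'
#' Validated bundle of every stage's settings for
#' \code{\link{run_pipeline}}.
#'
#' @param cohort A \code{\link{cohort_config}} (its seed drives every
#'   simulated draw).
#' @param exercises Exercises to run.
#' @param tap_params,gait_params Detector settings.
#' @param screening A \code{\link{screening_config}}.
#' @param ridge Ridge stabilizer for the logistic models.
#' @param out_dir Optional output directory; when given, stage artifacts
#'   and a manifest are written there.
#' @param write_trials Also write every simulated trial CSV (slow; off by
#'   default).
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(cohort = cohort_config(),
                       exercises = mcdt_exercises(),
                       tap_params = tap_detector_params(),
                       gait_params = gait_detector_params(),
                       screening = screening_config(),
                       ridge = 1e-6,
                       out_dir = NULL,
                       write_trials = FALSE) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(screening, "screening_config"))
  bad <- setdiff(exercises, mcdt_exercises())
  if (length(bad)) {
    stop("unknown exercise(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(cohort = cohort, exercises = exercises,
                 tap_params = tap_params, gait_params = gait_params,
                 screening = screening, ridge = ridge, out_dir = out_dir,
                 write_trials = write_trials),
            class = "run_config")
}

#' Run the full MCDT pipeline
#'
#' Orchestrates simulate -> extract -> dual-task cost -> pooled index ->
#' classify -> describe. With an \code{out_dir}, writes the participant
#' table, tidy feature and cost tables, pooled indices, per-model JSON
#' reports, a summary CSV and a manifest (seed, package version, file
#' hashes).
#'
#' @param cfg A \code{\link{run_config}}.
#' @return List with \code{cohort}, \code{features} (tidy),
#'   \code{responses}, \code{dtc}, \code{pooled}, \code{reports} (one per
#'   exercise x problem), \code{summary} (Table-shaped metrics frame) and
#'   \code{describe}.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  ccfg <- cfg$cohort
  study <- simulate_study(ccfg, exercises = cfg$exercises)
  records <- lapply(study$trials, function(tr) {
    r <- tr$recording
    list(participant_id = r$participant_id, exercise = r$exercise,
         cl = r$cl,
         features = process_trial(r, cfg$tap_params, cfg$gait_params,
                                  still_s = ccfg$still_s,
                                  distance_m = ccfg$distance_m))
  })
  features <- build_feature_table(records)
  dtc_tab <- weighted_dtc_table(features, study$responses)
  labels <- stats::setNames(as.character(study$cohort$group),
                            study$cohort$id)
  pooled <- build_pooled_indices(dtc_tab, labels, cfg$screening)
  reports <- list()
  for (ex in cfg$exercises) {
    for (problem in c("binary", "ternary")) {
      key <- paste(ex, problem, sep = "_")
      reports[[key]] <- tryCatch(
        classification_report(pooled, study$cohort, ex, problem,
                              ridge = cfg$ridge),
        error = function(e) {
          warning("classification failed for ", key, ": ",
                  conditionMessage(e))
          NULL
        })
    }
  }
  summary_df <- do.call(rbind, lapply(Filter(Negate(is.null), reports),
                                      report_summary_row))
  res <- list(cohort = study$cohort, features = features,
              responses = study$responses, dtc = dtc_tab, pooled = pooled,
              reports = reports, summary = summary_df,
              describe = describe_cohort(study$cohort))
  if (!is.null(cfg$out_dir)) write_artifacts(res, cfg)
  invisible(res)
}

report_summary_row <- function(rep) {
  if (rep$problem == "binary") {
    data.frame(exercise = rep$exercise, problem = "OA vs MCI",
               sensitivity = rep$metrics_pct[["sensitivity"]],
               specificity = rep$metrics_pct[["specificity"]],
               accuracy = rep$metrics_pct[["accuracy"]],
               recall = NA, precision = NA, f1 = NA,
               stringsAsFactors = FALSE)
  } else {
    data.frame(exercise = rep$exercise, problem = "OA vs SCI vs MCI",
               sensitivity = NA, specificity = NA,
               accuracy = rep$metrics_pct[["accuracy"]],
               recall = rep$metrics_pct[["recall"]],
               precision = rep$metrics_pct[["precision"]],
               f1 = rep$metrics_pct[["f1"]],
               stringsAsFactors = FALSE)
  }
}

write_artifacts <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(obj, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(res$cohort, "participants.csv")
  wr(res$features, "features.csv")
  wr(feature_table_wide(res$features), "features_wide.csv")
  wr(res$responses, "responses.csv")
  wr(res$dtc, "dtc.csv")
  wr(res$pooled$scores, "pooled_indices.csv")
  if (!is.null(res$summary)) wr(res$summary, "model_summary.csv")
  sel <- lapply(res$pooled$selection, function(s) {
    list(selected = s$selected, trace = s$trace)
  })
  selp <- file.path(cfg$out_dir, "selection_report.json")
  jsonlite::write_json(sel, selp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths[["selection_report.json"]] <- selp
  reps <- lapply(Filter(Negate(is.null), res$reports), function(r) {
    list(exercise = r$exercise, problem = r$problem, n = r$n,
         confusion = unclass(r$confusion),
         confusion_row_pct = attr(r$confusion, "row_pct"),
         metrics = as.list(if (r$problem == "binary") r$metrics
                           else r$metrics$weighted),
         metrics_pct = as.list(r$metrics_pct))
  })
  repp <- file.path(cfg$out_dir, "model_reports.json")
  jsonlite::write_json(reps, repp, auto_unbox = TRUE, digits = NA)
  paths[["model_reports.json"]] <- repp
  if (isTRUE(cfg$write_trials)) {
    tdir <- file.path(cfg$out_dir, "trials")
    dir.create(tdir, showWarnings = FALSE)
    for (j in seq_len(nrow(res$cohort))) {
      p <- res$cohort[j, ]
      for (ex in cfg$exercises) {
        for (cl in mcdt_cl_levels()) {
          tr <- generate_trial(p, ex, cl, cfg$cohort)
          write_trial(tr$recording,
                      file.path(tdir, trial_filename(p$id, ex, cl)))
        }
      }
    }
  }
  manifest <- list(
    seed = cfg$cohort$seed,
    package_version = as.character(utils::packageVersion("mcdtkit")),
    r_version = R.version.string,
    exercises = cfg$exercises,
    files = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
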