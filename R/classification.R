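#' Model specification for diagnostic classification
#'
#' @param predictors Ordered predictor names (pooled index of one
#'   exercise, age, FAB by default).
#' @param outcome \code{"binary"} (MCI vs OA) or \code{"ternary"}
#'   (OA vs SCI vs MCI).
#' @param ridge Small L2 weight-decay on the standardized predictors,
#'   guaranteeing finite coefficients under (quasi-)separation in tiny
#'   leave-one-out folds.
#' @return A list of class \code{"model_spec"}.
#' @export
model_spec <- function(predictors = c("score", "age", "fab"),
                       outcome = c("binary", "ternary"),
                       ridge = 1e-6) {
  outcome <- match.arg(outcome)
  stopifnot(length(predictors) >= 1, ridge >= 0)
  structure(list(predictors = predictors, outcome = outcome, ridge = ridge),
            class = "model_spec")
}

prepare_xy <- function(X, y, spec) {
  X <- as.data.frame(X)[, spec$predictors, drop = FALSE]
  y <- factor(y, levels = intersect(mcdt_groups(), unique(as.character(y))))
  ok <- stats::complete.cases(X) & !is.na(y)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with missing predictors or labels dropped")
  }
  list(X = X[ok, , drop = FALSE], y = droplevels(y[ok]), kept = which(ok))
}

#' Fit a (multinomial) logistic model
#'
#' Binary problems use a binomial logit, ternary problems a single
#' multinomial logit; both are fit with \code{nnet::multinom} on
#' internally standardized predictors, with the spec's ridge as weight
#' decay. Rows with missing predictors are dropped with a warning.
#'
#' @param X Predictor data.frame/matrix.
#' @param y Diagnosis labels (subset of OA/SCI/MCI).
#' @param spec A \code{\link{model_spec}}.
#' @return List of class \code{"mcdt_logit"} with the fitted model and the
#'   standardization used.
#' @export
fit_logistic <- function(X, y, spec = model_spec()) {
  pr <- prepare_xy(X, y, spec)
  if (nlevels(pr$y) < 2) stop("need at least 2 classes in y", call. = FALSE)
  ctr <- colMeans(pr$X)
  scl <- vapply(pr$X, stats::sd, numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- as.data.frame(scale(pr$X, center = ctr, scale = scl))
  dat <- cbind(Xs, .y = pr$y)
  fit <- nnet::multinom(.y ~ ., data = dat, decay = spec$ridge,
                        trace = FALSE, maxit = 500)
  structure(list(fit = fit, center = ctr, scale = scl,
                 levels = levels(pr$y), spec = spec),
            class = "mcdt_logit")
}

#' Predicted class probabilities and labels
#'
#' @param object A fitted \code{mcdt_logit}.
#' @param newdata Predictor data.frame.
#' @param ... Unused.
#' @return data.frame of class probabilities with a \code{.class} column;
#'   probability ties resolve to the first class in the fixed
#'   (OA, SCI, MCI) order.
#' @export
predict.mcdt_logit <- function(object, newdata, ...) {
  Xs <- as.data.frame(scale(as.data.frame(newdata)[, names(object$center),
                                                   drop = FALSE],
                            center = object$center, scale = object$scale))
  pp <- predict(object$fit, newdata = Xs, type = "probs")
  if (length(object$levels) == 2) {
    # 2-class multinom returns P(second level) as a vector
    pp <- cbind(1 - as.numeric(pp), as.numeric(pp))
  } else if (is.null(dim(pp))) {
    pp <- matrix(pp, nrow = 1) # single-row prediction
  }
  pp <- matrix(pp, ncol = length(object$levels),
               dimnames = list(NULL, object$levels))
  cls <- object$levels[max.col(pp, ties.method = "first")]
  out <- as.data.frame(pp)
  out$.class <- factor(cls, levels = object$levels)
  out
}

#' Leave-one-out cross-validated predictions
#'
#' Refits the model n times, each time holding out a single participant,
#' and predicts the held-out label with a model never shown that row.
#' Standardization is recomputed inside every training fold.
#'
#' @inheritParams fit_logistic
#' @return Factor of n out-of-sample predicted labels (NA where the row
#'   had missing predictors).
#' @export
loocv_predict <- function(X, y, spec = model_spec()) {
  pr <- prepare_xy(X, y, spec)
  n <- nrow(pr$X)
  k <- nlevels(pr$y)
  if (n < k + 2) stop("too few observations for leave-one-out", call. = FALSE)
  preds <- rep(NA_character_, length(y))
  for (i in seq_len(n)) {
    ytr <- droplevels(pr$y[-i])
    if (nlevels(ytr) < nlevels(pr$y)) {
      warning("a class vanished from a training fold; predicting among ",
              "the remaining classes")
    }
    m <- suppressWarnings(
      fit_logistic(pr$X[-i, , drop = FALSE], ytr, spec))
    preds[pr$kept[i]] <-
      as.character(predict(m, pr$X[i, , drop = FALSE])$.class)
  }
  factor(preds, levels = levels(pr$y))
}

#' Confusion matrix with fixed class order
#'
#' @param y_true,y_pred Label vectors drawn from \code{classes}.
#' @param classes Class order (rows = true, columns = predicted).
#' @return Integer K x K matrix; attribute \code{"row_pct"} holds the
#'   row-percentage form.
#' @export
confusion_matrix <- function(y_true, y_pred,
                             classes = intersect(mcdt_groups(),
                                                 unique(c(as.character(y_true),
                                                          as.character(y_pred))))) {
  yt <- as.character(y_true); yp <- as.character(y_pred)
  keep <- !is.na(yt) & !is.na(yp)
  yt <- yt[keep]; yp <- yp[keep]
  if (length(yt) && !all(c(yt, yp) %in% classes)) {
    stop("labels outside the declared class set", call. = FALSE)
  }
  cm <- table(factor(yt, levels = classes), factor(yp, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  rs <- rowSums(cm)
  pct <- sweep(cm, 1, ifelse(rs == 0, 1, rs), "/") * 100
  attr(cm, "row_pct") <- pct
  cm
}

#' Binary classification metrics (positive class MCI)
#'
#' @param cm 2 x 2 confusion matrix (rows true, columns predicted) whose
#'   dimnames include the positive class.
#' @param positive Positive class label (default \code{"MCI"}).
#' @return Named vector \code{sensitivity}, \code{specificity},
#'   \code{accuracy} in percent (unrounded).
#' @export
binary_metrics <- function(cm, positive = "MCI") {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  stopifnot(nrow(cm) == 2, positive %in% rownames(cm))
  negative <- setdiff(rownames(cm), positive)
  tp <- cm[positive, positive]; fn <- cm[positive, negative]
  tn <- cm[negative, negative]; fp <- cm[negative, positive]
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / sum(cm))
}

#' Multiclass classification metrics
#'
#' Per-class recall (diagonal over row sum), precision (diagonal over
#' column sum) and F1 (harmonic mean), plus support-weighted averages and
#' overall accuracy. A class with zero true support has undefined recall
#' (\code{NA} with a warning) and weight zero in the averages.
#'
#' @param cm K x K confusion matrix, rows true, columns predicted.
#' @return List with \code{per_class} (data.frame) and \code{weighted}
#'   (named vector \code{recall}, \code{precision}, \code{f1},
#'   \code{accuracy}), all in percent.
#' @export
multiclass_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  support <- rowSums(cm)
  if (any(support == 0)) {
    warning("class(es) with zero support: ",
            paste(rownames(cm)[support == 0], collapse = ", "))
  }
  recall <- ifelse(support == 0, NA_real_, diag(cm) / support) * 100
  colsum <- colSums(cm)
  precision <- ifelse(colsum == 0, NA_real_, diag(cm) / colsum) * 100
  f1 <- ifelse(is.na(recall) | is.na(precision) | (recall + precision) == 0,
               NA_real_, 2 * recall * precision / (recall + precision))
  w <- support / sum(support)
  wavg <- function(v) sum(v * w, na.rm = TRUE) / sum(w[!is.na(v)])
  list(per_class = data.frame(class = rownames(cm), recall = recall,
                              precision = precision, f1 = f1,
                              support = as.integer(support),
                              row.names = NULL),
       weighted = c(recall = wavg(recall), precision = wavg(precision),
                    f1 = wavg(f1),
                    accuracy = 100 * sum(diag(cm)) / sum(cm)))
}

#' Cross-validated classification report for one exercise
#'
#' Assembles the predictor set (pooled index, age, FAB), runs
#' leave-one-out cross-validation and computes the confusion matrix and
#' metric suite for the requested problem.
#'
#' @param pooled \code{pooled_index_table} (or its \code{scores} frame).
#' @param cohort Participant table with \code{id}, \code{group},
#'   \code{age}, \code{fab}.
#' @param exercise Which exercise's pooled index to use.
#' @param problem \code{"binary"} (MCI vs OA) or \code{"ternary"}.
#' @param ridge Ridge stabilizer passed to the model spec.
#' @return List of class \code{"mcdt_report"}: \code{spec},
#'   \code{confusion} (counts; row-percent in its attribute),
#'   \code{metrics} (raw) and \code{metrics_pct} (rounded to integer
#'   percent, the reporting convention), \code{n}.
#' @export
classification_report <- function(pooled, cohort, exercise,
                                  problem = c("binary", "ternary"),
                                  ridge = 1e-6) {
  problem <- match.arg(problem)
  scores <- if (inherits(pooled, "pooled_index_table")) pooled$scores else pooled
  sc <- scores[scores$exercise == exercise, ]
  dat <- merge(sc, cohort, by.x = "participant_id", by.y = "id")
  if (problem == "binary") dat <- dat[dat$group %in% c("OA", "MCI"), ]
  dat$group <- droplevels(factor(dat$group, levels = mcdt_groups()))
  spec <- model_spec(outcome = problem, ridge = ridge)
  preds <- loocv_predict(dat[, c("score", "age", "fab")], dat$group, spec)
  cm <- confusion_matrix(dat$group, preds, classes = levels(dat$group))
  metrics <- if (problem == "binary") binary_metrics(cm)
             else multiclass_metrics(cm)
  metrics_pct <- if (problem == "binary") round(metrics)
                 else round(metrics$weighted)
  structure(list(exercise = exercise, problem = problem, spec = spec,
                 confusion = cm, metrics = metrics,
                 metrics_pct = metrics_pct, n = sum(cm)),
            class = "mcdt_report")
}

#' @export
print.mcdt_report <- function(x, ...) {
  cat(sprintf("<mcdt_report> %s, %s problem, n = %d (LOOCV)\n", x$exercise,
              x$problem, x$n))
  print(x$confusion)
  cat("metrics (%):\n")
  print(x$metrics_pct)
  invisible(x)
}
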