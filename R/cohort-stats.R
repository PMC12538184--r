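#' Pearson chi-square test of independence
#'
#' Uncorrected (no Yates continuity correction) Pearson X^2 on an R x C
#' contingency table, with expected counts from the row/column margins and
#' df = (R-1)(C-1).
#'
#' @param tab Matrix (or table) of nonnegative counts, at least 2 x 2.
#' @return List with \code{statistic}, \code{df} and \code{p_value}.
#' @examples
#' sex <- rbind(female = c(6, 7, 13), male = c(4, 10, 4))
#' chi_square_independence(sex)$statistic # 4.38
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a zero margin makes expected counts undefined", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H across >= 2 groups, df = number of groups - 1. When
#' every value is identical the tie correction degenerates; 0 is returned
#' with a warning.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with \code{statistic} (H), \code{df} and \code{p_value}.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic # 7.2
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty", call. = FALSE)
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) {
    warning("all values identical; H degenerates to 0")
    return(list(statistic = 0, df = length(groups) - 1, p_value = 1))
  }
  res <- stats::kruskal.test(groups)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison; exact where the implementation allows
#' (small samples without ties), tie-corrected normal approximation
#' otherwise. The U statistic counts pairs where an \code{x} value exceeds
#' a \code{y} value, so \code{x} entirely below \code{y} gives U = 0.
#'
#' @param x,y Numeric vectors.
#' @return List with \code{statistic} (U) and \code{p_value}.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Bonferroni-corrected critical p value
#'
#' @param alpha Familywise error rate (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_critical(0.05, 3) # 0.0167
#' @export
bonferroni_critical <- function(alpha = 0.05, m) {
  if (missing(m) || length(m) != 1 || m < 1) {
    stop("m must be a positive number of comparisons", call. = FALSE)
  }
  alpha / m
}

iqr7 <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))

#' Descriptive cohort summary with group tests
#'
#' Per-group counts and percentages, median (IQR, linear-interpolation
#' quartiles) of age and FAB, sex and education breakdowns, plus the
#' inferential suite: chi-square for sex and education, Kruskal-Wallis
#' for age and FAB with pairwise Mann-Whitney post hocs at the
#' Bonferroni-corrected critical p.
#'
#' @param participants Participant table (see
#'   \code{\link{generate_cohort}}).
#' @return List of class \code{"mcdt_cohort_summary"}: \code{n},
#'   \code{by_group} (data.frame), \code{sex_table},
#'   \code{education_table}, \code{tests}, \code{posthoc},
#'   \code{bonferroni_p}.
#' @export
describe_cohort <- function(participants) {
  stopifnot(nrow(participants) > 0)
  p <- participants
  groups <- levels(droplevels(p$group))
  by_group <- do.call(rbind, lapply(groups, function(g) {
    s <- p[p$group == g, ]
    data.frame(group = g, n = nrow(s), pct = 100 * nrow(s) / nrow(p),
               age_median = stats::median(s$age), age_iqr = iqr7(s$age),
               fab_median = stats::median(s$fab), fab_iqr = iqr7(s$fab),
               stringsAsFactors = FALSE)
  }))
  sex_tab <- table(p$sex, p$group)[, groups, drop = FALSE]
  edu_tab <- table(p$education, p$group)[, groups, drop = FALSE]
  tests <- list()
  if (length(groups) >= 2 && all(rowSums(sex_tab) > 0)) {
    tests$sex_chisq <- tryCatch(chi_square_independence(sex_tab),
                                error = function(e) NULL)
    tests$education_chisq <- tryCatch(chi_square_independence(edu_tab),
                                      error = function(e) NULL)
    tests$age_kw <- kruskal_wallis(split(p$age, droplevels(p$group)))
    tests$fab_kw <- kruskal_wallis(split(p$fab, droplevels(p$group)))
  }
  posthoc <- NULL
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    posthoc <- do.call(rbind, lapply(pairs, function(pr) {
      mw_age <- mann_whitney(p$age[p$group == pr[1]], p$age[p$group == pr[2]])
      mw_fab <- mann_whitney(p$fab[p$group == pr[1]], p$fab[p$group == pr[2]])
      data.frame(contrast = paste(pr, collapse = " vs "),
                 age_p = mw_age$p_value, fab_p = mw_fab$p_value)
    }))
  }
  structure(list(n = nrow(p), by_group = by_group, sex_table = sex_tab,
                 education_table = edu_tab, tests = tests,
                 posthoc = posthoc,
                 bonferroni_p = if (length(groups) >= 2)
                   bonferroni_critical(0.05, choose(length(groups), 2))
                 else NA_real_),
            class = "mcdt_cohort_summary")
}

#' @export
print.mcdt_cohort_summary <- function(x, ...) {
  cat("<mcdt_cohort_summary> N =", x$n, "\n")
  print(x$by_group, row.names = FALSE)
  if (!is.null(x$tests$sex_chisq)) {
    cat(sprintf("sex: X2 = %.2f (df %d); education: X2 = %.2f (df %d)\n",
                x$tests$sex_chisq$statistic, x$tests$sex_chisq$df,
                x$tests$education_chisq$statistic, x$tests$education_chisq$df))
    cat(sprintf("age: H = %.2f (df %d, p = %.3f); FAB: H = %.2f (df %d, p = %.3f)\n",
                x$tests$age_kw$statistic, x$tests$age_kw$df,
                x$tests$age_kw$p_value, x$tests$fab_kw$statistic,
                x$tests$fab_kw$df, x$tests$fab_kw$p_value))
  }
  invisible(x)
}
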