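test_that("Spearman matrix honours rank invariances", {
  withr::with_seed(4, x <- rnorm(20))
  m <- spearman_matrix(data.frame(a = x, b = exp(3 * x), c = -x))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1)  # strictly monotone transform
  expect_equal(m["a", "c"], -1) # perfect inversion
  expect_equal(spearman_matrix(data.frame(x = 1:4, y = 4:1))["x", "y"], -1)
  expect_warning(spearman_matrix(data.frame(a = 1:6,
                                            b = c(1, 2, NA, NA, NA, NA),
                                            c = 6:1)),
                 "non-missing")
})

test_that("Cohen's d matches its closed form", {
  expect_equal(cohens_d(c(1, 2, 3, 1, 2, 3),
                        rep(c("A", "B"), each = 3))$d, 0)
  expect_equal(cohens_d(c(1, 2, 3, 3, 4, 5),
                        rep(c("A", "B"), each = 3))$d, -2)
  expect_error(cohens_d(c(1, 2, 3), c("A", "A", "B")), "2 members")
})

screen_labels <- factor(rep(c("OA", "MCI"), each = 10),
                        levels = mcdt_groups())

test_that("uncorrelated pools survive screening untouched", {
  withr::with_seed(5, pool <- data.frame(p = rnorm(20), q = rnorm(20),
                                         r = rnorm(20)))
  stopifnot(max(abs(spearman_matrix(pool)[upper.tri(diag(3))])) < 0.4)
  scr <- screen_features(pool, screen_labels)
  expect_setequal(scr$selected, c("p", "q", "r"))
  expect_equal(nrow(scr$trace), 0)
})

test_that("the most-redundant column is deleted first", {
  withr::with_seed(6, {
    b <- rnorm(20); c_ <- rnorm(20)
    pool <- data.frame(A = b + c_ + rnorm(20, 0, 0.2), B = b, C = c_)
  })
  rho <- spearman_matrix(pool)
  stopifnot(abs(rho["A", "B"]) >= 0.4, abs(rho["A", "C"]) >= 0.4,
            abs(rho["B", "C"]) < 0.4)
  scr <- screen_features(pool, screen_labels)
  expect_setequal(scr$selected, c("B", "C"))
  expect_equal(scr$trace$deleted, "A")
  expect_equal(scr$trace$rule, "max high-rho count")
})

test_that("count ties are broken by the lower effect size", {
  withr::with_seed(7, {
    base <- rnorm(20)
    mci <- screen_labels == "MCI"
    pool <- data.frame(lo = base + 0.25 * mci + rnorm(20, 0, 0.15),
                       hi = base + 1.2 * mci)
  })
  rho <- spearman_matrix(pool)
  stopifnot(abs(rho["lo", "hi"]) >= 0.4)
  d_lo <- abs(cohens_d(pool$lo[screen_labels %in% c("MCI", "OA")],
                       droplevels(screen_labels))$d)
  d_hi <- abs(cohens_d(pool$hi, droplevels(screen_labels))$d)
  stopifnot(d_lo < d_hi)
  scr <- screen_features(pool, screen_labels)
  expect_equal(scr$selected, "hi")
  expect_equal(scr$trace$rule, "lower |Cohen d| (MCI vs OA)")
})

test_that("residual ties fall back to the priority list", {
  withr::with_seed(8, x <- rnorm(20))
  pool <- data.frame(X1 = x, X2 = x) # identical: same counts, same |d|
  scr <- screen_features(pool, screen_labels,
                         screening_config(priority_list = "X2"))
  expect_equal(scr$selected, "X2")
  expect_equal(scr$trace$rule, "priority list")
})

test_that("survivors never share |rho| above the threshold", {
  withr::with_seed(9, {
    for (i in 1:8) {
      k <- sample(4:9, 1)
      base <- matrix(rnorm(20 * 3), 20, 3)
      pool <- as.data.frame(base[, sample(3, k, replace = TRUE)] +
                              matrix(rnorm(20 * k, 0, 0.6), 20, k))
      names(pool) <- paste0("v", seq_len(k))
      scr <- screen_features(pool, screen_labels)
      expect_lte(length(scr$selected), 6)
      expect_lte(nrow(scr$trace), k - 1) # terminates in <= pool size - 1
      if (length(scr$selected) > 1) {
        rho <- spearman_matrix(pool[, scr$selected, drop = FALSE])
        expect_lt(max(abs(rho[upper.tri(rho)])), 0.4)
      }
    }
  })
})

test_that("more than six clean components are capped by effect size", {
  withr::with_seed(10, {
    pool <- as.data.frame(matrix(rnorm(40 * 8), 40, 8))
    names(pool) <- paste0("v", 1:8)
  })
  labels <- factor(rep(c("OA", "MCI"), each = 20), levels = mcdt_groups())
  rho <- spearman_matrix(pool)
  stopifnot(max(abs(rho[upper.tri(rho)])) < 0.4)
  scr <- screen_features(pool, labels)
  expect_equal(length(scr$selected), 6)
})

test_that("orientation is explicit, never defaulted", {
  expect_equal(orient_higher_better(c(1, -2), "tap"), c(1, -2))
  expect_equal(orient_higher_better(c(1, -2), "exc_sd"), c(-1, 2))
  expect_error(orient_higher_better(1, "mystery"), "orientation map")
})

test_that("pooled scores are bounded averages of normalized components", {
  one <- pooled_score(data.frame(a = c(0, 2, 4)))
  expect_equal(one$score, c(0, 0.5, 1))
  two <- pooled_score(data.frame(a = c(0, 0.2, 1), b = c(0, 0.6, 1)))
  expect_equal(two$score[2], 0.4) # mean of 0.2 and 0.6
  expect_equal(two$score[3], 1)   # at the sample max on every component
  # invariant to increasing affine rescaling of a raw component
  withr::with_seed(11, x <- data.frame(a = rnorm(15), b = rnorm(15)))
  y <- x; y$a <- 100 + 7 * y$a
  expect_equal(pooled_score(x)$score, pooled_score(y)$score,
               tolerance = 1e-12)
  expect_warning(ps <- pooled_score(data.frame(a = c(1, NA), b = c(2, NA))),
                 "missing every component")
  expect_true(is.na(ps$score[2]))
})
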