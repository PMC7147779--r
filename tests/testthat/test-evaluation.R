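test_that("survey sample size follows the finite-population formula", {
  inf <- sample_size(Inf)
  expect_equal(inf$n, 1.96^2 * 0.25 / 0.05^2, tolerance = 1e-12)  # 384.16
  fin <- sample_size(8770)
  n0 <- 1.96^2 * 0.25 / 0.05^2
  expect_equal(fin$n, n0 / (1 + n0 / 8770), tolerance = 1e-12)
  expect_equal(fin$n, 368.04, tolerance = 1e-4)
  expect_equal(fin$n_ceiling, 369)
  # monotone decreasing in the margin of error
  ns <- sapply(c(0.02, 0.05, 0.1), function(e) sample_size(8770, e = e)$n)
  expect_true(all(diff(ns) < 0))
  expect_error(sample_size(-1), "N > 0")
  expect_error(sample_size(100, p = 0), "N > 0")
})

test_that("Cohen's kappa on canonical tables", {
  a <- c("x", "x", "y", "y")
  expect_equal(cohens_kappa(a, a), 1)
  expect_equal(cohens_kappa(matrix(c(1, 1, 1, 1), 2)), 0)  # exactly chance
  # 2x2 (20,5;10,65): po = .85, pe = .6 -> kappa = .625
  expect_equal(cohens_kappa(matrix(c(20, 10, 5, 65), 2)), 0.625)
  expect_true(is.na(cohens_kappa(matrix(c(4, 0, 0, 0), 2))))  # pe = 1
  expect_error(cohens_kappa(matrix(1:6, 2)), "square")
})

test_that("chi-square association with Pearson residual identity", {
  indep <- outer(c(10, 20), c(3, 7)) / 1  # proportional to margins
  expect_equal(chi_square_association(indep)$statistic, 0, tolerance = 1e-12)

  diag2 <- matrix(c(10, 0, 0, 10), 2)
  r <- chi_square_association(diag2)
  expect_equal(r$statistic, 20)
  expect_equal(sum(r$residuals^2), r$statistic, tolerance = 1e-9)

  set.seed(10)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    rr <- chi_square_association(tab)
    expect_equal(sum(rr$residuals^2), rr$statistic, tolerance = 1e-9)
  }
  expect_error(chi_square_association(matrix(c(1, 1, 0, 0), 2)), "degenerate")
})

test_that("group tests reproduce hand arithmetic and the F = t^2 identity", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6))
  g <- rep(c("a", "b"), each = 3)
  r <- group_tests(df, g)
  # means 2 vs 5, pooled sd 1 -> t = -3 / sqrt(2/3) = -3.674235
  expect_equal(r$t_stat, -3.674235, tolerance = 1e-6)
  expect_equal(r$f_stat, r$t_stat^2, tolerance = 1e-9)

  set.seed(20)
  rnd <- data.frame(x = rnorm(40), y = rnorm(40, sd = 3))
  rg <- rep(c("a", "b"), 20)
  rr <- group_tests(rnd, rg)
  expect_equal(rr$f_stat, rr$t_stat^2, tolerance = 1e-9)

  same <- group_tests(data.frame(v = rep(1, 8)), rep(c("a", "b"), 4))
  expect_true(same$degenerate)

  # bonferroni stars: p = 0.04 passes 0.05 but not 0.05/223
  set.seed(99)
  found <- FALSE
  for (i in 1:50) {
    d <- data.frame(v = rnorm(30))
    gg <- rep(c("a", "b"), 15)
    rt <- group_tests(d, gg)
    if (!is.na(rt$p_value) && rt$p_value > 0.01 && rt$p_value < 0.05) {
      expect_true(rt$sig_05); expect_false(rt$sig_bonferroni)
      found <- TRUE; break
    }
  }
  expect_true(found)

  expect_error(group_tests(data.frame(v = 1:3), c("a", "a", "b")), "n >= 2")
})

test_that("emotion/text correlation screen masks non-significant pairs", {
  set.seed(30)
  x <- rnorm(60)
  face <- cbind(sadface = x, joyface = rnorm(60))
  text <- cbind(sadtext = x + rnorm(60, 0, 0.4), negemo = rnorm(60))
  r <- emotion_text_correlation(face, face)
  expect_equal(diag(r$r), c(1, 1), ignore_attr = TRUE)
  expect_false(any(diag(r$masked)))

  rt <- emotion_text_correlation(face, text)
  expect_false(rt$masked["sadface", "sadtext"])
  expect_gt(rt$r["sadface", "sadtext"], 0.7)

  const <- cbind(flat = rep(1, 60))
  rc <- emotion_text_correlation(const, text)
  expect_true(all(rc$masked))
  expect_true(all(is.na(rc$r)))

  # independent noise at n = 50: small correlations, mostly masked
  set.seed(31)
  noise <- emotion_text_correlation(matrix(rnorm(200), 50), matrix(rnorm(200), 50))
  expect_gt(mean(noise$masked), 0.6)
  expect_lt(max(abs(noise$r)), 0.5)
})

test_that("classifier metrics use depressed as the positive class", {
  truth <- c(1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 0, 0, 0, 0, 1)
  m <- classifier_metrics(truth, pred)
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  expect_equal(unname(m["specificity"]), 3 / 4)
  expect_equal(unname(m["f1"]), 2 * (2 / 3) * (2 / 3) / (2 / 3 + 2 / 3))
  expect_equal(unname(m["accuracy"]), 5 / 7)
})

test_that("cross-validation is stratified, leakage-free and calibrated on nulls", {
  set.seed(40)
  ids <- sprintf("u%03d", 1:60)
  y <- setNames(rep(c(1, 0), 30), ids)
  oracle <- data.frame(user_id = ids, perfect = ifelse(y == 1, 1, -1) + rnorm(60, 0, 0.01))
  cv <- cross_validate(list(a = oracle), y, booster_params(nrounds = 10), k = 5, seed = 3)
  expect_equal(unname(cv$mean), rep(1, 4), tolerance = 1e-12)
  expect_equal(nrow(cv$folds), 5)

  noise <- data.frame(user_id = ids, x1 = rnorm(60), x2 = rnorm(60))
  cvn <- cross_validate(list(a = noise), y, booster_params(nrounds = 10), k = 5, seed = 3)
  expect_lt(abs(unname(cvn$mean["accuracy"]) - 0.5), 0.25)

  expect_error(cross_validate(list(a = oracle), y, k = 40), "minority class")

  # same seed, same folds, same numbers
  cv2 <- cross_validate(list(a = oracle), y, booster_params(nrounds = 10), k = 5, seed = 3)
  expect_identical(cv$folds, cv2$folds)
})
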