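test_that("one-way ANOVA handles degenerate groups and equals t-squared for two", {
  flat <- suppressWarnings(oneway_anova(list(a = c(2, 2), b = c(2, 2))))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(10)
  x <- stats::rnorm(12, 5)
  y <- stats::rnorm(15, 6)
  f <- oneway_anova(list(a = x, b = y))
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(f$statistic, unname(t2), tolerance = 1e-9)
  expect_equal(f$df, c(1, 25))

  expect_error(oneway_anova(list(a = 1:3)), "two groups")
  expect_error(oneway_anova(list(a = 1, b = 1:3)), "two values")
})

test_that("ANOVA is invariant to permutation within groups", {
  set.seed(11)
  g <- list(a = stats::rnorm(8), b = stats::rnorm(8, 1), c = stats::rnorm(8))
  f1 <- oneway_anova(g)
  f2 <- oneway_anova(lapply(g, sample))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
})

test_that("seasonal ANOVA on default synthetic sediment detects the season effect", {
  cal <- default_calibration()
  hits <- 0L
  n_runs <- 200L
  for (i in seq_len(n_runs)) {
    sed <- gen_sediment(cal, seed = 7000 + i, particles = FALSE)
    g <- sed$abundances[sed$abundances$site == "S1", ]
    p <- oneway_anova(split(g$abundance, g$season))$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.8)
})

test_that("ANOVA type-I error is calibrated under a no-season-effect generator", {
  cal <- degenerate_calibration(mean_value = 300)
  for (site in c("S1", "S2")) for (season in names(cal$sediment_abundance[[site]]))
    cal$sediment_abundance[[site]][[season]] <- c(mean = 300, sd = 40)
  rejections <- 0L
  n_runs <- 400L
  for (i in seq_len(n_runs)) {
    sed <- gen_sediment(cal, seed = 20000 + i, particles = FALSE,
                        n_replicates = 10)
    g <- sed$abundances[sed$abundances$site == "S1", ]
    p <- oneway_anova(split(g$abundance, g$season))$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_runs
  tol <- 3 * sqrt(0.05 * 0.95 / n_runs)
  expect_lt(abs(rate - 0.05), tol)
})

test_that("chi-square matches the closed-form sum over (O-E)^2/E", {
  z <- sizeclass_chisq(c(a = 10, b = 20), c(a = 20, b = 10))
  # hand oracle on the 2x2 table
  tab <- rbind(c(10, 20), c(20, 10))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(z$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(z$df, 1)

  same <- sizeclass_chisq(c(a = 30, b = 30), c(a = 30, b = 30))
  expect_equal(same$statistic, 0)
})

test_that("chi-square merges classes with tiny expected counts deterministically", {
  a <- c(small = 0L, mid = 50L, big = 50L)
  b <- c(small = 1L, mid = 40L, big = 60L)
  z <- sizeclass_chisq(a, b)
  expect_equal(z$df, 1)                       # 3 classes merged to 2
  expect_true(any(grepl("\\+", z$groups)))    # merged label reported
  expect_error(sizeclass_chisq(c(a = 1), c(b = 1)), "identical")
})

test_that("pearson correlation matches its covariance definition", {
  x <- 1:6
  expect_equal(pearson_r(x, 2 * x + 1)$estimate[["r"]], 1)

  set.seed(12)
  a <- stats::rnorm(10)
  b <- stats::rnorm(10)
  r <- pearson_r(a, b)$estimate[["r"]]
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, oracle, tolerance = 1e-12)

  expect_equal(pearson_r(a, b, rank = TRUE)$test_name,
               "spearman correlation")
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("univariate regression equals the normal-equation oracle", {
  exact <- suppressWarnings(univariate_regression(1:5, 3 * (1:5) - 2))
  expect_equal(exact$estimate,
               c(slope = 3, intercept = -2, r_squared = 1))

  set.seed(13)
  x <- stats::rnorm(20)
  y <- 1.5 * x + stats::rnorm(20, sd = 0.3)
  fit <- univariate_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$estimate[["slope"]], slope, tolerance = 1e-12)
  expect_equal(fit$estimate[["intercept"]], intercept, tolerance = 1e-12)
})

test_that("instar comparison reports per-instar moments and burden/head-width links", {
  ex <- gen_instar_experiment(default_calibration(), seed = 71)
  l2 <- ex$larvae[ex$larvae$instar == "L2", ]
  l4 <- ex$larvae[ex$larvae$instar == "L4", ]
  rep <- compare_instars(l2, l4)
  expect_equal(nrow(rep$summary), 12L)   # 6 variables x 2 instars
  expect_s3_class(rep$burden_test, "mp_test")

  # burdens exactly proportional to head width -> r = 1 in the zero-noise limit
  l2$burden <- l2$head_capsule_width_mm * 10
  l4$burden <- l4$head_capsule_width_mm * 10
  expect_equal(compare_instars(l2, l4)$headwidth_cor$estimate[["r"]], 1,
               tolerance = 1e-9)
  expect_error(compare_instars(l2[0, ], l4), "non-empty")
})
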