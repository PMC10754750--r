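cal <- default_calibration()

test_that("generator output is a pure function of (calibration, seed)", {
  a <- gen_sediment(cal, seed = 11)
  b <- gen_sediment(cal, seed = 11)
  expect_identical(a, b)
  c <- gen_sediment(cal, seed = 12)
  expect_false(identical(a$abundances$abundance, c$abundances$abundance))

  sed <- a$abundances
  l1 <- gen_larvae(cal, sed, seed = 11)
  l2 <- gen_larvae(cal, sed, seed = 11)
  expect_identical(l1, l2)
  t1 <- gen_tubes(cal, sed, seed = 11)
  t2 <- gen_tubes(cal, sed, seed = 11)
  expect_identical(t1, t2)
})

test_that("zero-sd calibration degenerates to the exact (quantised) means", {
  dcal <- degenerate_calibration(mean_value = 300)
  sed <- gen_sediment(dcal, seed = 1, particles = FALSE)
  expect_true(all(sed$abundances$abundance == 300))
})

test_that("generated sizes never violate the configured truncation bounds", {
  sed <- gen_sediment(cal, seed = 3)
  p <- sed$particles
  for (sh in c("fiber", "fragment")) {
    ld <- cal$length_dists[[sh]]
    wl <- cal$width_dists[[sh]]
    len <- p$length_um[p$shape == sh]
    expect_true(all(len >= ld[["lower"]] & len <= ld[["upper"]]))
    if (sh == "fragment") {
      w <- p$width_um[p$shape == sh]
      expect_true(all(w >= wl[["lower"]] & w <= wl[["upper"]]))
    }
  }
})

test_that("empirical compositions converge to the calibration vectors", {
  sed <- gen_sediment(cal, seed = 5)
  p <- sed$particles
  for (site in c("S1", "S2")) {
    ps <- p[p$site == site, ]
    n <- nrow(ps)
    expect_gt(n, 1e4)
    for (attr in c("shape", "color", "polymer")) {
      target <- if (attr == "color") cal$color_proportions$sediment
                else cal[[paste0(attr, "_proportions")]]$sediment[[site]]
      emp <- table(factor(ps[[attr]], levels = names(target))) / n
      tol <- 3 * sqrt(pmax(target * (1 - target), 1e-6) / n)
      expect_true(all(abs(as.numeric(emp) - target) <= tol + 1e-12),
                  label = paste("composition convergence", site, attr))
    }
  }
})

test_that("regressing cell burdens on sediment abundance recovers the coupling slope", {
  sed <- gen_sediment(cal, seed = 21, particles = FALSE)
  larv <- gen_larvae(cal, sed$abundances, seed = 21, particles = FALSE,
                     n_subsamples = 200)   # 2000 larvae per cell
  cells <- stats::aggregate(abundance ~ site + season, sed$abundances, mean)
  bm <- stats::aggregate(burden ~ site + season, larv$larvae, mean)
  m <- merge(cells, bm, by = c("site", "season"))
  fit <- univariate_regression(m$abundance, m$burden)
  slope <- fit$estimate[["slope"]]
  se <- abs(slope) / sqrt(fit$statistic)   # slope se from the F statistic
  expect_lt(abs(slope - cal$larva_coupling[["slope"]]), 2 * se)
})

test_that("zero coupling slope makes burdens independent of sediment abundance", {
  flat <- cal
  flat$larva_coupling <- c(intercept = 0.7, slope = 0)
  sed <- gen_sediment(flat, seed = 31, particles = FALSE)
  larv <- gen_larvae(flat, sed$abundances, seed = 31, particles = FALSE,
                     n_subsamples = 50)
  cells <- stats::aggregate(abundance ~ site + season, sed$abundances, mean)
  bm <- stats::aggregate(burden ~ site + season, larv$larvae, mean)
  m <- merge(cells, bm, by = c("site", "season"))
  r <- pearson_r(m$abundance, m$burden)$estimate[["r"]]
  expect_lt(abs(r), 0.9)   # 8 points: the null 95% band excludes 0.9
})

test_that("identity selectivity reproduces the sediment length distribution", {
  flat <- cal
  flat$selectivity[["floor"]] <- 1    # constant weight 1
  sed <- gen_sediment(flat, seed = 41)
  larv <- gen_larvae(flat, sed$abundances, seed = 41, n_subsamples = 50)
  ks <- suppressWarnings(
    stats::ks.test(larv$particles$length_um, sed$particles$length_um))
  expect_gt(ks$p.value, 0.001)
})

test_that("second-instar larvae ingest only fibers below the length cap", {
  sed <- gen_sediment(cal, seed = 51, particles = FALSE)
  larv <- gen_larvae(cal, sed$abundances, seed = 51, instar = "L2")
  expect_true(all(larv$particles$shape == "fiber"))
  expect_true(all(larv$particles$length_um <=
                    cal$instar$L2$fiber_length[["upper"]]))
})

test_that("tubes: zero sediment and zero intercept give zero burdens; negative means warn", {
  zcal <- cal
  zcal$tube_coupling <- c(intercept = 0, slope = 0.002)
  zero_sed <- make_abundances(rep(0L, 3))
  zero_sed <- do.call(rbind, lapply(c("S1", "S2"), function(s)
    do.call(rbind, lapply(c("winter", "spring", "summer", "autumn"),
                          function(se) make_abundances(rep(0L, 3), site = s,
                                                       season = se)))))
  tb <- gen_tubes(zcal, zero_sed, seed = 1, particles = FALSE)
  expect_true(all(tb$tubes$burden == 0))

  ncal <- cal
  ncal$larva_coupling <- c(intercept = -10, slope = 0.001)
  sed <- gen_sediment(cal, seed = 1, particles = FALSE)
  w <- capture_warnings(
    lv <- gen_larvae(ncal, sed$abundances, seed = 1, particles = FALSE))
  expect_gte(length(w), 1L)        # one clip warning per affected cell
  expect_true(all(grepl("clipped", w)))
  expect_true(all(lv$larvae$burden == 0))
})

test_that("the instar experiment respects the calibrated design and ordering", {
  ex <- gen_instar_experiment(cal, seed = 61)
  expect_equal(nrow(ex$larvae), 200L)
  l2 <- ex$larvae[ex$larvae$instar == "L2", ]
  l4 <- ex$larvae[ex$larvae$instar == "L4", ]
  # L4 morphometric means exceed L2 means under the default calibration
  for (v in c("weight_mg", "body_length_mm", "head_capsule_width_mm",
              "head_capsule_length_mm", "mentum_width_mm"))
    expect_gt(mean(l4[[v]]), mean(l2[[v]]))
  p2 <- ex$particles[ex$particles$replicate_id %in% l2$replicate_id, ]
  expect_true(all(p2$shape == "fiber"))
  expect_equal(sum(ex$larvae$burden), nrow(ex$particles))
})
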