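test_that("abundance summary matches a two-pass oracle and is permutation invariant", {
  set.seed(9)
  counts <- as.integer(round(stats::runif(1e4, 100, 900)))
  a <- make_abundances(counts)
  s <- summarize_abundance(a, by = c("site", "season"))
  # brute-force two-pass mean/sd
  m <- sum(a$abundance) / nrow(a)
  v <- sum((a$abundance - m)^2) / (nrow(a) - 1)
  expect_equal(s$mean, m, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(v), tolerance = 1e-12)
  expect_equal(s$n_replicates, 1e4)

  shuffled <- a[sample(nrow(a)), ]
  expect_equal(summarize_abundance(shuffled, by = c("site", "season")), s,
               ignore_attr = TRUE)
})

test_that("a single replicate summarises to sd 0 and mean = value", {
  s <- summarize_abundance(make_abundances(346L), by = c("site", "season"))
  expect_equal(s$mean, 346)
  expect_equal(s$sd, 0)
})

test_that("mixed basis units within a group are rejected", {
  a <- rbind(make_abundances(c(3L, 4L), site = "S1", season = "winter",
                             matrix = "tube", basis_unit = "tube"),
             make_abundances(c(5L, 6L), site = "S1", season = "winter",
                             matrix = "tube", basis = 0.9,
                             basis_unit = "g_wet_tube"))
  expect_error(summarize_abundance(a, by = c("site", "season")),
               "mixed basis units")
})

test_that("pooled seasonal mean is the unweighted mean of the site means", {
  # the winter convention: site means 345.8 and 380 pool to 363 +/- 24
  s <- data.frame(site = c("S1", "S2"), season = "winter",
                  mean = c(345.8, 380))
  pooled <- pool_site_means(s)
  expect_equal(pooled$mean, 362.9)
  expect_equal(round(pooled$mean), 363)
  expect_equal(round(pooled$sd), 24)
})

test_that("length binning partitions particles with the half-open convention", {
  p <- data.frame(length_um = c(400, 700, 1200, 1800, 2300))
  b <- bin_lengths(p)
  expect_equal(b$proportion[1:5], rep(0.2, 5))
  expect_equal(sum(b$count), nrow(p))

  # boundary: exactly 500 -> first class; 500.5 -> second
  b2 <- bin_lengths(data.frame(length_um = c(500, 500.5)))
  expect_equal(b2$count[1:2], c(1L, 1L))

  # overflow class is emitted for lengths above the top edge
  b3 <- bin_lengths(data.frame(length_um = 2600))
  expect_equal(b3$count[b3$size_class == ">2500"], 1L)
})

test_that("binning agrees with an independent linear-scan histogram oracle", {
  set.seed(4)
  len <- stats::runif(1000, 1, 2600)
  edges <- c(500, 1000, 1500, 2000, 2500)
  oracle <- integer(6)
  for (x in len) {                      # linear scan, no vectorised cut()
    k <- 1L
    for (e in edges) if (x > e) k <- k + 1L
    oracle[k] <- oracle[k] + 1L
  }
  b <- bin_lengths(data.frame(length_um = len), edges_um = edges)
  expect_identical(b$count, oracle)
  expect_equal(sum(b$count), length(len))
})

test_that("compositions are exhaustive, zero-padded and sum to one", {
  p <- make_particles(50)
  p$shape <- "fiber"
  cshape <- composition(p, "shape")
  expect_equal(cshape$proportion[cshape$category == "fiber"], 1)
  expect_equal(cshape$proportion[cshape$category == "fragment"], 0)
  expect_equal(sum(cshape$proportion), 1)

  # the sediment colour panel: counts 35/23/22/13/7 -> exact proportions
  cols <- c(rep("blue", 35), rep("red", 23), rep("black", 22),
            rep("green", 13), rep("other", 7))
  p2 <- make_particles(100)
  p2$color <- cols
  ccol <- composition(p2, "color")
  got <- stats::setNames(ccol$proportion, ccol$category)
  expect_equal(unname(got[c("blue", "red", "black", "green", "other")]),
               c(0.35, 0.23, 0.22, 0.13, 0.07))

  by_site <- composition(make_particles(500), "polymer", by = "site")
  sums <- tapply(by_site$proportion, by_site$site, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("detection rate counts units with at least one particle", {
  expect_equal(detection_rate(c(rep(1L, 95), rep(0L, 5))), 0.95)
  expect_equal(detection_rate(rep(0L, 10)), 0)
  expect_equal(detection_rate(c(1L, 2L, 5L)), 1)
  expect_error(detection_rate(integer(0)), "at least one")
  expect_error(detection_rate(c(1, -1)), "non-negative")
})
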