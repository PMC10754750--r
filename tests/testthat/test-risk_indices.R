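ref <- survey_reference()

test_that("contamination factor reproduces the reported winter and summer cells", {
  expect_equal(report_cf(contamination_factor(345.8)), 193)  # S1 winter
  expect_equal(report_cf(contamination_factor(470)), 263)    # S2 summer
  expect_equal(contamination_factor(1.79), 1)
  expect_error(contamination_factor(100, co = 0), "co")
  expect_error(contamination_factor(-1), "ci")
})

test_that("pollution load index and its report rounding reproduce 13.5 and 15", {
  expect_equal(pollution_load_index(1), 1)
  expect_equal(pollution_load_index(4), 2)
  # annual S1: CF 180.5 -> displayed 181 -> sqrt(181) = 13.45 -> 13.5
  cf_s1 <- contamination_factor(mean(ref$seasonal_ci$S1))
  expect_equal(report_pli(cf_s1), 13.5)
  # annual S2: CF 211.8 -> displayed 212 (>= 200) -> integer 15
  cf_s2 <- contamination_factor(mean(ref$seasonal_ci$S2))
  expect_equal(report_pli(cf_s2), 15)
})

test_that("polymer hazard index works on the percent scale with closed score lookups", {
  expect_equal(polymer_hazard_index(c(PES = 93, PP = 7)), 400)  # S2 winter
  expect_equal(polymer_hazard_index(c(PE = 100)), 1100)
  expect_equal(polymer_hazard_index(c(PES = 96, PP = 3, PE = 1)), 407)
  expect_error(polymer_hazard_index(c(PES = 90, PS = 10)), "PS")
  expect_error(polymer_hazard_index(numeric(0)), "empty")
  expect_error(polymer_hazard_index(c(PES = 60, PP = 20)), "sum")
  # reported compositions may drift by rounding within +/- 0.5
  expect_silent(polymer_hazard_index(c(PES = 96.3, PP = 4)))
})

test_that("toxicity coefficient H/Ci reproduces the reported table cells", {
  expect_equal(report_tj(toxicity_coefficient(400, 380)), 1.05)  # S2 winter
  expect_equal(report_tj(toxicity_coefficient(460, 379.05)), 1.21) # S2 year
  expect_equal(toxicity_coefficient(123, 123), 1)
  # further cells: printed at 1-2 decimals, all within 0.05
  cells <- list(c(519, 312, 1.7), c(449, 470, 0.96), c(463, 251.4, 1.8),
                c(470.7, 354.2, 1.33), c(416, 323.1, 1.28))
  for (cell in cells)
    expect_lt(abs(toxicity_coefficient(cell[1], cell[2]) - cell[3]), 0.05)
  expect_error(toxicity_coefficient(400, 0), "undefined")
})

test_that("ecological risk index reproduces the reported cells at full precision", {
  cf <- contamination_factor(380)            # S2 winter
  tj <- toxicity_coefficient(400, 380)
  expect_equal(report_ri(ecological_risk_index(tj, cf)), 223)
  cf <- contamination_factor(312)            # S2 spring
  tj <- toxicity_coefficient(519, 312)
  expect_equal(report_ri(ecological_risk_index(tj, cf)), 290)
  expect_equal(ecological_risk_index(0, 100), 0)
})

test_that("category tables classify the reported values and every boundary", {
  expect_equal(as.character(classify_pli(13.5)), "II")
  expect_equal(pli_label(classify_pli(13.5)), "medium")
  expect_equal(as.character(classify_pli(9.99)), "I")
  expect_equal(as.character(classify_pli(35)), "IV")

  expect_equal(as.character(classify_h(416)), "III")
  expect_equal(as.character(classify_h(9.99)), "I")
  expect_equal(as.character(classify_h(c(10, 100, 1000, 1001))),
               c("II", "III", "IV", "IV"))

  expect_equal(as.character(classify_ri(232)), "II")
  expect_equal(as.character(classify_ri(149.9)), "I")
  expect_equal(as.character(classify_ri(c(150, 300, 600, 1200, 1300))),
               c("II", "III", "IV", "V", "V"))
})

test_that("the annual S2 profile reproduces the reported 1-year row", {
  p <- risk_profile(ci = ref$seasonal_ci$S2, h = 460, site = "S2",
                    period = "year")
  expect_equal(report_cf(p$CF), 212)
  expect_equal(report_pli(p$CF), 15)
  expect_equal(report_tj(p$Tj), 1.21)
  expect_equal(report_ri(p$RI), 257)
  expect_equal(p$pli_category, "II")
  expect_equal(p$h_level, "III")
  expect_equal(p$ri_level, "II")
  expect_match(render_table1(p)[2],
               "212, 15 (medium), 460 (level III), 1.21, 257 (level II)",
               fixed = TRUE)
})

test_that("degenerate profiles error and empty renders are header-only", {
  expect_error(risk_profile(ci = c(0, 0, 0, 0), h = 400), "undefined|> 0")
  expect_length(render_table1(NULL), 1L)
  p <- risk_profile(ci = 400, h = 400 * 1.79 * 1300 / 400)  # force RI level V
  expect_match(render_table1(p)[2], "(level V)", fixed = TRUE)
})

test_that("scaling Ci moves CF, PLI and Tj but never RI", {
  set.seed(2)
  for (i in 1:20) {
    ci <- stats::runif(1, 10, 1000)
    h <- stats::runif(1, 50, 1200)
    co <- stats::runif(1, 0.5, 5)
    p1 <- risk_profile(ci, h = h, co = co)
    p2 <- risk_profile(2 * ci, h = h, co = co)
    expect_equal(p2$CF, 2 * p1$CF, tolerance = 1e-12)
    expect_equal(p2$PLI, sqrt(2) * p1$PLI, tolerance = 1e-12)
    expect_equal(p2$Tj, p1$Tj / 2, tolerance = 1e-12)
    expect_equal(p2$RI, p1$RI, tolerance = 1e-12)
    expect_equal(p1$RI, h / co, tolerance = 1e-9)  # RI = H/Co identity
  }
})

test_that("indices are monotone and H is invariant to merging equal-score polymers", {
  ci <- seq(10, 1000, by = 90)
  expect_true(all(diff(contamination_factor(ci)) > 0))
  expect_true(all(diff(pollution_load_index(contamination_factor(ci))) > 0))
  # reallocating percent from a low-score to a high-score polymer raises H
  h_lo <- polymer_hazard_index(c(PES = 90, PE = 10))
  h_hi <- polymer_hazard_index(c(PES = 80, PE = 20))
  expect_gt(h_hi, h_lo)
  # PES and PP share Sn = 4: merging them leaves H unchanged
  split_h <- polymer_hazard_index(c(PES = 50, PP = 43, PE = 7))
  merged_h <- polymer_hazard_index(c(PES = 93, PE = 7))
  expect_equal(split_h, merged_h)
})
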