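test_that("RVA arithmetic and scale invariance hold", {
  expect_equal(compute_rva(1.0, 10), 1.0)
  expect_equal(compute_rva(8.0, 20), 1.0)
  expect_equal(compute_rva(0.74, 7.3), 1.239, tolerance = 5e-4)

  set.seed(5)
  for (i in 1:25) {
    v <- runif(1, 0.2, 3); d <- runif(1, 4, 15); s <- runif(1, 0.1, 10)
    expect_lt(abs(compute_rva(v * s^3, d * s) - compute_rva(v, d)) /
                compute_rva(v, d), 1e-12)
  }
  expect_error(compute_rva(0, 10), "positive")
  expect_error(compute_rva(1, -1), "positive")
})

test_that("between-breed CV uses the n-1 SD over the mean of means", {
  expect_equal(round(compute_cv(c(30.2, 27.8, 32.2, 22.4, 20.5, 20.3)), 2),
               0.20)
  expect_equal(round(compute_cv(c(34.9, 29.2, 31.2, 25.7, 19.1, 21.4)), 2),
               0.22)
  expect_equal(compute_cv(c(5, 5, 5)), 0)
  # invariance under positive rescaling of all means
  x <- c(8.5, 8.3, 8.9, 7.4, 7.0, 7.7)
  expect_equal(compute_cv(x * 3.7), compute_cv(x), tolerance = 1e-12)
  expect_error(compute_cv(7), "at least 2")
  expect_error(compute_cv(c(-1, 1)), "zero")
})

test_that("correlation bands partition |r| with left-closed intervals", {
  expect_identical(classify_correlation(0.84), "very strong")
  expect_identical(classify_correlation(0.47), "moderate")
  expect_identical(classify_correlation(0.0), "very weak")
  expect_identical(classify_correlation(0.79), "strong")
  expect_identical(classify_correlation(0.8), "very strong")
  expect_identical(classify_correlation(c(0.2, 0.4, 0.6, 1.0)),
                   c("weak", "moderate", "strong", "very strong"))
  # sign symmetry
  r <- seq(-1, 1, by = 0.13)
  expect_identical(classify_correlation(r), classify_correlation(-r))
  expect_error(classify_correlation(1.2), "\\[-1, 1\\]")
})

test_that("weight classes split at 20 kg with the boundary in heavy", {
  expect_identical(as.character(weight_class(c(7.9, 19.99, 20, 36.4))),
                   c("light", "light", "heavy", "heavy"))
  expect_error(weight_class(-3), "positive")
})

test_that("reference tables use interpolated order statistics and stay monotone", {
  mk <- function(values, side = "left", w = 10) {
    n <- length(values)
    data.frame(weight_kg = rep(w, n), side = side, m = values)
  }
  # constant stratum: all five quantiles equal the constant
  rt <- build_reference_table(mk(rep(1, 8)), metrics = "m", min_n = 5)
  expect_true(all(unlist(rt[, c("p10", "q1", "median", "q3", "p90")]) == 1))

  # odd-length median
  rt2 <- build_reference_table(mk(1:11), metrics = "m", min_n = 5)
  expect_equal(rt2$median, 6)

  # 1..10 under type-7 interpolation: hand-computed h = 1 + (n-1)p
  rt3 <- build_reference_table(mk(1:10), metrics = "m", min_n = 5)
  expect_equal(rt3$p10, 1.9)
  expect_equal(rt3$p90, 9.1)

  # monotonicity on arbitrary data
  set.seed(6)
  df <- data.frame(weight_kg = runif(80, 5, 40),
                   side = rep(c("left", "right"), 40),
                   m = rlnorm(80))
  rt4 <- build_reference_table(df, metrics = "m", min_n = 5)
  expect_true(all(rt4$p10 <= rt4$q1 & rt4$q1 <= rt4$median &
                    rt4$median <= rt4$q3 & rt4$q3 <= rt4$p90))

  # an undersized stratum is omitted with a warning
  df5 <- rbind(mk(1:8), mk(1:3, w = 30))
  expect_warning(rt5 <- build_reference_table(df5, metrics = "m", min_n = 5),
                 "omitted")
  expect_false("heavy" %in% rt5$weight_class)
})

test_that("assessment flags values against the stratified and universal limits", {
  ref <- data.frame(
    weight_class = rep(c("heavy", "light"), each = 3),
    side = "left",
    metric = rep(c("volume_cm3", "rva", "caudal_h_mm"), 2),
    n = 30,
    p10 = c(0.89, 0.83, 7.26, 0.47, 0.93, 6.37),
    q1 = c(1.1, 0.9, 8.0, 0.6, 1.0, 6.8),
    median = c(1.41, 0.98, 8.62, 0.74, 1.25, 7.38),
    q3 = c(1.6, 1.1, 9.2, 0.8, 1.35, 7.8),
    p90 = c(1.68, 1.14, 9.73, 0.82, 1.44, 8.09),
    stringsAsFactors = FALSE)
  class(ref) <- c("reference_table", class(ref))

  # heavy dog, left caudal height 9.0: within the weight-specific band but
  # above the legacy 7.4 mm universal threshold
  m <- gland_measurement("left", length_mm = 30, cranial_height_mm = 12,
                         cranial_width_mm = 6, caudal_height_mm = 9.0,
                         caudal_width_mm = 7, isthmus_height_mm = 5,
                         isthmus_width_mm = 5, volume_cm3 = 1.5,
                         aorta_dv_mm = 11,
                         rva = compute_rva(1.5, 11))
  fl <- assess_against_reference(m, "heavy", ref)
  expect_identical(fl$flag[fl$metric == "caudal_h_mm"], "within")
  expect_true(attr(fl, "above_universal_threshold"))

  # light dog with RVA 1.5 against p90 = 1.44
  m2 <- gland_measurement("left", length_mm = 22, cranial_height_mm = 10,
                          cranial_width_mm = 6, caudal_height_mm = 7.0,
                          caudal_width_mm = 6, isthmus_height_mm = 5,
                          isthmus_width_mm = 5, volume_cm3 = 0.74,
                          aorta_dv_mm = 6.03, rva = 1.5)
  fl2 <- assess_against_reference(m2, "light", ref)
  expect_identical(fl2$flag[fl2$metric == "rva"], "above_p90")
  expect_identical(fl2$flag[fl2$metric == "volume_cm3"], "within")
  expect_false(attr(fl2, "above_universal_threshold"))

  expect_error(assess_against_reference(m, "heavy", ref[ref$side == "x", ]),
               "does not cover")
})

test_that("gland measurement invariants reject inconsistent records", {
  expect_error(gland_measurement("left", length_mm = 10,
                                 cranial_height_mm = 12, cranial_width_mm = 5,
                                 caudal_height_mm = 6, caudal_width_mm = 5,
                                 volume_cm3 = 1), "exceed")
  expect_error(gland_measurement("right", length_mm = 20,
                                 cranial_height_mm = 8, cranial_width_mm = 5,
                                 caudal_height_mm = 6, caudal_width_mm = 5,
                                 isthmus_height_mm = 4, volume_cm3 = 1),
               "left gland only")
  expect_error(gland_measurement("left", length_mm = -1,
                                 cranial_height_mm = 1, cranial_width_mm = 1,
                                 caudal_height_mm = 1, caudal_width_mm = 1,
                                 volume_cm3 = 1), "positive")
})
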