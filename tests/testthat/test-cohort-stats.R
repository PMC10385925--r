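test_that("the Shapiro-Wilk gate detects gross non-normality and holds its level", {
  set.seed(20)
  expect_false(normality_gate(runif(5000)))
  expect_error(normality_gate(rep(1, 10)), "degenerate")
  expect_error(normality_gate(c(1, 2)), "at least 3")

  # level: ~95% pass rate for genuinely normal samples
  pass <- vapply(1:300, function(i) {
    set.seed(i)
    normality_gate(rnorm(200))
  }, TRUE)
  expect_gt(mean(pass), 0.91)
  expect_lt(mean(pass), 0.99)
})

test_that("compare_breeds picks the branch the gate dictates", {
  set.seed(21)
  df_norm <- data.frame(breed = rep(c("a", "b", "c"), each = 30),
                        v = rnorm(90, rep(c(0, 0, 3), each = 30)))
  # force a clean parametric run by drawing until the gate passes
  repeat {
    df_norm$v <- rnorm(90, rep(c(0, 0, 3), each = 30))
    ok <- all(vapply(split(df_norm$v, df_norm$breed),
                     function(x) shapiro.test(x)$p.value >= 0.05, TRUE))
    if (ok) break
  }
  cb <- compare_breeds(df_norm, "v")
  expect_match(cb$report$test, "ANOVA")
  expect_true(cb$report$gate_normal)
  expect_false(letters_shared(cb$grouping, "a", "c"))
  expect_true(letters_shared(cb$grouping, "a", "b"))

  df_exp <- data.frame(breed = rep(c("a", "b", "c"), each = 40),
                       v = rexp(120) * rep(c(1, 1, 40), each = 40))
  cb2 <- compare_breeds(df_exp, "v")
  expect_match(cb2$report$test, "Kruskal")
  expect_false(cb2$report$gate_normal)
  expect_false(letters_shared(cb2$grouping, "a", "c"))

  expect_error(compare_breeds(df_norm[df_norm$breed == "a", ], "v"),
               "at least 2 breeds")
  df_small <- rbind(df_norm, data.frame(breed = "tiny", v = 1))
  expect_error(compare_breeds(df_small, "v"), "tiny")
})

test_that("gated breed comparison separates the weight classes under calibration", {
  vt <- calibration_volume_stats()
  bt <- calibration_breed_table()
  large <- c("German Shepherd", "Labrador Retriever", "Boxer")
  small <- setdiff(bt$breed, large)
  set.seed(22)
  n_rep <- 120
  separated <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    df <- data.frame(
      breed = rep(bt$breed, bt$n),
      v = rnorm(sum(bt$n), rep(vt$right_mean, bt$n),
                rep(vt$right_sd, bt$n)))
    cb <- compare_breeds(df, "v")
    separated[r] <- !any(vapply(large, function(a)
      any(vapply(small, function(b)
        letters_shared(cb$grouping, a, b), TRUE)), TRUE))
  }
  expect_gte(mean(separated), 0.95)
})

test_that("paired side tests handle identity, power and degenerate input", {
  df0 <- rbind(cohort_row("d1", "left"), cohort_row("d1", "right"),
               cohort_row("d2", "left"), cohort_row("d2", "right"))
  r0 <- side_difference(df0, "volume_cm3")
  expect_equal(r0$p_value, 1)

  # simulated attenuation offset: right = left + 9 HU, residual SD 6, n = 16
  detect <- vapply(1:500, function(s) {
    set.seed(s)
    left <- rnorm(16, 80, 15)
    right <- left + 9 + rnorm(16, 0, 6)
    df <- do.call(rbind, lapply(1:16, function(i)
      rbind(cohort_row(sprintf("d%02d", i), "left", hu = left[i]),
            cohort_row(sprintf("d%02d", i), "right", hu = right[i]))))
    side_difference(df, "mean_hu")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(detect), 0.90)

  expect_error(side_difference(rbind(cohort_row("d1", "left"),
                                     cohort_row("d1", "right")),
                               "volume_cm3"), "at least 2 pairs")
  expect_error(side_difference(rbind(df0, cohort_row("d3", "left")),
                               "volume_cm3"), "unpaired")
})

test_that("weight-group test is calibrated under the null and powered for RVA", {
  # null: identical distributions in both classes -> rejection near alpha
  set.seed(23)
  pnull <- vapply(1:300, function(i) {
    df <- data.frame(weight_kg = c(runif(30, 5, 19), runif(30, 21, 40)),
                     side = "left", m = rnorm(60))
    weight_group_difference(df, "m")$p_value
  }, 1)
  expect_lt(abs(mean(pnull < 0.05) - 0.05), 0.04)
  expect_gt(mean(pnull), 0.40)   # roughly uniform p-values
  expect_lt(mean(pnull), 0.60)

  # RVA shifted between classes as in the reference percentiles:
  # light median 1.25, heavy 0.98, spread matching the quartile widths
  pow <- vapply(1:200, function(s) {
    set.seed(s)
    df <- data.frame(
      weight_kg = c(runif(32, 5, 19), runif(34, 21, 40)),
      side = "left",
      m = c(rnorm(32, 1.25, 0.17), rnorm(34, 0.98, 0.15)))
    weight_group_difference(df, "m")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(pow), 0.95)

  dfall <- data.frame(weight_kg = runif(20, 25, 40), side = "left",
                      m = rnorm(20))
  expect_error(weight_group_difference(dfall, "m"), "nonempty")
})

test_that("weight correlations report exact and null behaviour", {
  df <- data.frame(weight_kg = seq(5, 40, length.out = 20), side = "left")
  df$m <- 2 * df$weight_kg
  r <- correlate_with_weight(df, "m")
  expect_equal(r$r, 1.0, tolerance = 1e-12)
  expect_identical(r$band, "very strong")

  set.seed(24)
  rs <- vapply(1:300, function(i) {
    d <- data.frame(weight_kg = runif(66, 5, 40), side = "left",
                    m = rnorm(66))
    correlate_with_weight(d, "m")$r
  }, 1)
  expect_lt(abs(mean(rs)), 0.05)
  expect_gte(mean(abs(rs) < 0.25), 0.95)

  dfc <- data.frame(weight_kg = rep(10, 5), side = "left", m = rnorm(5))
  expect_error(correlate_with_weight(dfc, "m"), "constant")
})

test_that("inclusion criteria exclude young, incomplete and inhomogeneous dogs", {
  df <- rbind(
    cohort_row("young", "left", age = 1.5), cohort_row("young", "right", age = 1.5),
    cohort_row("oneside", "left"),
    cohort_row("cloudy", "left", homogeneous = FALSE),
    cohort_row("cloudy", "right"),
    cohort_row("good", "left"), cohort_row("good", "right"))
  res <- apply_inclusion_criteria(df)
  expect_setequal(unique(res$kept$id), "good")
  expect_identical(res$excluded$reason[res$excluded$id == "young"], "age<2")
  expect_identical(res$excluded$reason[res$excluded$id == "oneside"],
                   "missing gland")
  expect_identical(res$excluded$reason[res$excluded$id == "cloudy"],
                   "non-homogeneous enhancement")
})
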