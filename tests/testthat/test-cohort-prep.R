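test_that("pulse pressure and mean arterial pressure follow their formulas", {
  expect_equal(pulse_pressure(140, 90), 50)
  expect_equal(pulse_pressure(120, 80), 40)
  expect_equal(mean_arterial_pressure(120, 90), 100)
  expect_equal(mean_arterial_pressure(150, 90), 110)
  expect_error(pulse_pressure(120, 120), "systolic")
  expect_error(mean_arterial_pressure(100, 100), "systolic")
  expect_error(pulse_pressure(100, -5), "positive")
})

test_that("BP composites are translation-equivariant", {
  set.seed(41)
  sbp <- runif(50, 110, 190)
  dbp <- sbp - runif(50, 20, 60)
  for (c_shift in c(-10, 5, 17.5)) {
    expect_equal(pulse_pressure(sbp + c_shift, dbp + c_shift),
                 pulse_pressure(sbp, dbp))
    expect_equal(mean_arterial_pressure(sbp + c_shift, dbp + c_shift),
                 mean_arterial_pressure(sbp, dbp) + c_shift)
  }
})

test_that("group assignment follows the history + 140/90 rule", {
  expect_equal(as.character(assign_group(TRUE, 150, 85)), "PMHTN")
  expect_equal(as.character(assign_group(FALSE, 120, 70)), "NTN")
  expect_equal(as.character(assign_group(TRUE, 130, 80)), "UNCLASSIFIED")
  # equality at the threshold satisfies neither strict rule
  expect_equal(as.character(assign_group(FALSE, 140, 80)), "UNCLASSIFIED")
  expect_equal(as.character(assign_group(TRUE, 140, 90)), "UNCLASSIFIED")
  # untreated but elevated
  expect_equal(as.character(assign_group(FALSE, 160, 95)), "UNCLASSIFIED")
  # diagnosed, elevated diastolic only
  expect_equal(as.character(assign_group(TRUE, 135, 95)), "PMHTN")
})

test_that("every valid record gets exactly one label", {
  set.seed(7)
  n <- 500
  sbp <- runif(n, 100, 200)
  dbp <- pmin(sbp - 1, runif(n, 55, 115))
  hist <- runif(n) < 0.5
  labs <- assign_group(hist, sbp, dbp)
  expect_equal(length(labs), n)
  expect_false(any(is.na(labs)))
  expect_true(all(labs %in% c("PMHTN", "NTN", "UNCLASSIFIED")))
})

test_that("cohort preparation averages readings and derives composites", {
  raw <- tibble::tibble(
    sBP_1 = c(150, 118), sBP_2 = c(146, 122),
    dBP_1 = c(92, 72), dBP_2 = c(88, 68),
    arm_curl_left = c(14, 18), arm_curl_right = c(16, 20),
    history_of_hypertension = c(TRUE, FALSE)
  )
  prep <- prepare_cohort(raw)
  expect_equal(prep$sBP, c(148, 120))
  expect_equal(prep$dBP, c(90, 70))
  expect_equal(prep$arm_curl, c(15, 19))
  expect_equal(prep$PP, c(58, 50))
  expect_equal(prep$mBP, c(90 + 58 / 3, 70 + 50 / 3))
  expect_equal(as.character(prep$group), c("PMHTN", "NTN"))
})

test_that("normal equal-variance samples are routed to the t-test branch", {
  picks <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    a <- tibble::tibble(x = rnorm(500))
    b <- tibble::tibble(x = rnorm(500))
    compare_groups(a, b)$test_used
  }, "")
  # with three independent gate tests at alpha = 0.05 the expected t-branch
  # rate is 0.95^2 * 0.95 ~ 0.857; allow Monte-Carlo slack around it
  expect_gt(mean(picks == "t_test"), 0.78)
  expect_lt(mean(picks == "t_test"), 0.93)
})

test_that("heavily skewed samples are routed to Mann-Whitney", {
  set.seed(21)
  a <- tibble::tibble(x = rlnorm(60, 0, 1))
  b <- tibble::tibble(x = rlnorm(60, 0.5, 1))
  row <- compare_groups(a, b)
  expect_equal(row$test_used, "mann_whitney")
  expect_false(is.na(row$z))
})

test_that("identical samples give null p-values and no effect size", {
  a <- tibble::tibble(x = c(rnorm(30, 1, 2)))
  row <- compare_groups(a, a)
  expect_gt(row$p_value, 0.9)
  expect_true(is.na(row$effect_size_r))
})

test_that("group order swap preserves p and flips the signed statistic", {
  set.seed(33)
  a <- tibble::tibble(x = rlnorm(40))
  b <- tibble::tibble(x = rlnorm(40, 0.8))
  r1 <- compare_groups(a, b)
  r2 <- compare_groups(b, a)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$z, -r2$z, tolerance = 1e-12)
  if (!is.na(r1$effect_size_r)) {
    expect_equal(r1$effect_size_r, -r2$effect_size_r, tolerance = 1e-12)
  }
})

test_that("variables with too few observations are skipped with a warning", {
  a <- tibble::tibble(x = c(1, 2, 3, NA, NA, NA, NA), y = rnorm(7))
  b <- tibble::tibble(x = rnorm(7), y = rnorm(7))
  expect_warning(out <- compare_groups(a, b), "fewer than 4")
  expect_false("x" %in% out$variable)
  expect_true("y" %in% out$variable)
})
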