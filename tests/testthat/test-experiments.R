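sim <- function(pop, sex, n, seed, shift = NULL) {
  simulate_collection(population_config(pop, sex, n, seed = seed, shift = shift))
}

test_that("a perfect estimator passes through the pipeline with zero error", {
  x <- simulate_collection(population_config("PT", "M", 60, seed = 50))
  est <- data.frame(individual_id = x$individual_id, age = x$age,
                    status = "estimated", point_estimate = as.numeric(x$age),
                    stringsAsFactors = FALSE)
  rep <- band_report(est)
  expect_true(all(rep$bias[rep$n > 0] == 0))
  expect_true(all(rep$absolute_error[rep$n > 0] == 0))
  expect_true(all(rep$no_estimation_count == 0))
})

test_that("run_experiment enforces sex-specific estimation", {
  ref <- sim("PT", "M", 100, seed = 51)
  test_f <- sim("PT", "F", 30, seed = 52)
  expect_error(run_experiment(ref, test_f), "sex")
})

test_that("matched synthetic reference/test recovers age with small bias", {
  ref <- sim("PT", "M", 300, seed = 53)
  test <- sim("PT", "M", 150, seed = 54)
  ex <- run_experiment(ref, test)
  g <- ex$report[ex$report$scope == "global", ]
  expect_lt(abs(g$bias), 2)
  expect_gt(g$absolute_error, 3)
  expect_lt(g$absolute_error, 12)
})

test_that("crossed design pairs only individuals estimated in both arms", {
  ref_a <- sim("PT", "M", 200, seed = 55)
  test_a <- sim("PT", "M", 100, seed = 56)
  ref_b <- sim("NA", "M", 200, seed = 57)
  test_b <- sim("NA", "M", 100, seed = 58)
  d <- run_crossed_design(ref_a, test_a, ref_b, test_b)
  cmp <- d$comparisons[d$comparisons$scope == "global", ]
  for (side in c("PT", "NA")) {
    ests <- d$estimates$M
    key_m <- if (side == "PT") "a.matched" else "b.matched"
    key_x <- if (side == "PT") "a.crossed" else "b.crossed"
    n_both <- sum(ests[[key_m]]$status == "estimated" &
                  ests[[key_x]]$status == "estimated")
    expect_equal(unique(cmp$n_paired[cmp$test_population == side]), n_both)
  }
})

test_that("crossed design is reproducible from fixed seeds", {
  args <- list(sim("PT", "F", 150, seed = 60), sim("PT", "F", 80, seed = 61),
               sim("NA", "F", 150, seed = 62), sim("NA", "F", 80, seed = 63))
  d1 <- do.call(run_crossed_design, args)
  d2 <- do.call(run_crossed_design, args)
  expect_identical(d1$inaccuracy, d2$inaccuracy)
  expect_identical(d1$comparisons, d2$comparisons)
})

test_that("exchangeable populations show no systematic matched/crossed gap", {
  # same generating process for both "populations": the crossed reference is
  # as good as the matched one, so the paired tests fire near the nominal rate
  ref_a <- sim("PT", "M", 200, seed = 64)
  test_a <- sim("PT", "M", 100, seed = 65)
  ref_b <- sim("PT", "M", 200, seed = 66)
  test_b <- sim("PT", "M", 100, seed = 67)
  d <- run_crossed_design(ref_a, test_a, ref_b, test_b)
  g <- d$comparisons[d$comparisons$scope == "global", ]
  gap <- abs(g$matched_mean - g$crossed_mean)
  expect_true(all(gap < 2.5))
})

test_that("population shift drives the crossed bias directions", {
  ref_a <- sim("PT", "M", 250, seed = 68)          # slower-aging
  test_a <- sim("PT", "M", 150, seed = 69)
  ref_b <- sim("NA", "M", 250, seed = 70, shift = -6)  # faster-aging
  test_b <- sim("NA", "M", 150, seed = 71, shift = -6)
  d <- run_crossed_design(ref_a, test_a, ref_b, test_b)
  g <- d$inaccuracy[d$inaccuracy$scope == "global", ]
  # slower-aging test under faster-aging reference is underestimated
  expect_lt(g$bias[g$arm == "crossed" & g$test_population == "PT"], 0)
  # faster-aging test under slower-aging reference is overestimated
  expect_gt(g$bias[g$arm == "crossed" & g$test_population == "NA"], 0)
})

test_that("no-estimation summaries reproduce the published worked example", {
  pub <- published_no_estimation_counts()
  s <- summarize_no_estimates(pub)
  expect_equal(s$matched_mean, 1)
  expect_equal(s$crossed_mean, 6.75)
  # all estimated everywhere -> both means 0
  zero <- pub
  zero$no_estimation_count <- 0L
  s0 <- summarize_no_estimates(zero)
  expect_equal(s0$matched_mean, 0)
  expect_equal(s0$crossed_mean, 0)
})

test_that("published anchor tables are internally consistent", {
  anchors <- stage_age_anchors()
  # per variable, stage counts sum to the sample size of the group
  sizes <- c(PT.M = 294, `NA.M` = 456, PT.F = 317, `NA.F` = 370)
  for (key in names(sizes)) {
    ps <- strsplit(key, ".", fixed = TRUE)[[1]]
    sub <- anchors[anchors$population == ps[1] & anchors$sex == ps[2], ]
    per_var <- tapply(sub$n, sub$variable, sum)
    expect_true(all(per_var == sizes[[key]]), label = key)
  }
  # decade-bin age structure sums to the same totals
  struct <- collection_age_structure()
  tot <- tapply(struct$n, paste(struct$population, struct$sex, sep = "."), sum)
  expect_equal(tot[names(sizes)], sizes, ignore_attr = TRUE)
})
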