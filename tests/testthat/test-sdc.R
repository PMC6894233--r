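test_that("SDC formula matches hand arithmetic and scales correctly", {
  est <- smallest_detectable_change(c(-1, 1), k = 2)
  expect_equal(est$sdc_mm3, 1.96 / sqrt(2), tolerance = 1e-12)
  expect_equal(est$sd_change_scores, sqrt(2), tolerance = 1e-12)

  expect_equal(smallest_detectable_change(rep(0, 5))$sdc_mm3, 0)

  set.seed(14)
  cs <- rnorm(50, 0, 0.4)
  base <- smallest_detectable_change(cs, k = 2)$sdc_mm3
  # homogeneity: scaling the scores scales the SDC
  expect_equal(smallest_detectable_change(3 * cs, k = 2)$sdc_mm3, 3 * base)
  expect_equal(smallest_detectable_change(-2 * cs, k = 2)$sdc_mm3, 2 * base)
  # k-scaling law holds exactly
  for (k in c(3, 4, 8))
    expect_equal(smallest_detectable_change(cs, k = k)$sdc_mm3,
                 base * sqrt(2 / k), tolerance = 1e-12)

  expect_error(smallest_detectable_change(1), "at least 2")
  expect_error(smallest_detectable_change(c(1, 2), k = 1), "k")
})

test_that("SDC estimation is calibrated against simulated reader noise", {
  sigma <- 0.5
  truth <- rep(4, 10000)
  rd <- simulate_repeated_readings(truth, reading_sd = sigma, k = 2, seed = 21)
  est <- smallest_detectable_change(reading_change_scores(rd), k = 2)
  # change scores have SD sigma*sqrt(2), so SDC -> 1.96*sigma/sqrt(2)
  expect_lt(abs(est$sdc_mm3 - 1.96 * sigma / sqrt(2)),
            0.05 * 1.96 * sigma / sqrt(2))
})

test_that("classification against the SDC uses strict exceedance", {
  expect_equal(as.character(classify_lesion_change(0.6, 0.5)), "progression")
  expect_equal(as.character(classify_lesion_change(0.5, 0.5)), "stable")
  expect_equal(as.character(classify_lesion_change(-0.5, 0.5)), "stable")
  expect_equal(as.character(classify_lesion_change(-0.4, 0.3)), "regression")
  expect_equal(as.character(classify_lesion_change(0.1, 0.5, is_new = TRUE)),
               "progression")
  expect_error(classify_lesion_change(1, -0.5), "non-negative")
})

test_that("classification partitions lesions and is monotone in delta", {
  set.seed(15)
  delta <- rnorm(10000, 0.3, 1.2)
  sdc <- sample(c(0.3, 0.5), 10000, replace = TRUE)
  cat1 <- classify_lesion_change(delta, sdc)
  expect_equal(sum(table(cat1)), 10000)
  # increasing any delta never moves a lesion toward regression
  rank_of <- c(progression = 3, stable = 2, regression = 1)
  cat2 <- classify_lesion_change(delta + abs(rnorm(10000)), sdc)
  expect_true(all(rank_of[as.character(cat2)] >= rank_of[as.character(cat1)]))
})

test_that("dynamics summaries reproduce proportion arithmetic", {
  dyn <- data.frame(
    lesion_id = sprintf("L%03d", 1:111),
    kind = "erosion",
    delta_mm3 = c(rep(1.9, 34), rep(1.2, 3), rep(0.1, 64), rep(-1.4, 10)),
    is_new = rep(c(FALSE, TRUE, FALSE, FALSE), c(34, 3, 64, 10)))
  dyn$category <- classify_lesion_change(dyn$delta_mm3, 0.5, dyn$is_new)
  s <- summarize_dynamics(dyn)
  expect_equal(s$proportion_pct[s$category == "progression"], 33.3)
  expect_equal(s$proportion_pct[s$category == "stable"], 57.7)
  expect_equal(s$n[s$category == "regression"], 10)
  expect_equal(sum(s$n), 111)

  # single stable lesion: 100%, SD not available
  one <- data.frame(lesion_id = "L1", kind = "erosion", delta_mm3 = 0,
                    is_new = FALSE)
  one$category <- classify_lesion_change(0, 0.5)
  s1 <- summarize_dynamics(one)
  expect_equal(s1$proportion_pct[s1$category == "stable"], 100)
  expect_equal(s1$mean_delta_mm3[s1$category == "stable"], 0)
  expect_true(is.na(s1$sd_delta_mm3[s1$category == "stable"]))
  expect_error(summarize_dynamics(one[0, ]), "empty")
})

test_that("cumulative-probability series is ordered and self-consistent", {
  dyn <- data.frame(lesion_id = c("c", "a", "b"), kind = "erosion",
                    delta_mm3 = c(0.6, -0.7, 0.0), is_new = FALSE)
  dyn$category <- classify_lesion_change(dyn$delta_mm3, 0.5)
  cp <- cumulative_probability_data(dyn)
  expect_equal(cp$delta_mm3, c(-0.7, 0.0, 0.6))
  expect_equal(cp$rank, 1:3)

  # all-equal deltas: stable order by lesion id
  dyn2 <- dyn
  dyn2$delta_mm3 <- 0.2
  cp2 <- cumulative_probability_data(dyn2)
  expect_equal(cp2$lesion_id, c("a", "b", "c"))

  # categories attached to the series agree with direct classification
  spec <- cohort_spec(seed = 30)
  sim <- simulate_cohort(spec)
  dyn3 <- lesion_dynamics(sim$lesions)
  cp3 <- cumulative_probability_data(dyn3)
  for (kd in unique(cp3$kind)) {
    sub <- cp3[cp3$kind == kd, ]
    expect_equal(nrow(sub), sum(dyn3$kind == kd))
    expect_false(is.unsorted(sub$delta_mm3))
    m <- match(sub$lesion_id, dyn3$lesion_id)
    expect_equal(as.character(sub$category), as.character(dyn3$category[m]))
  }
})
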