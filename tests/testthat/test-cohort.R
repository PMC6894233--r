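test_that("DAPSA scoring sums its five components and bands tile [0, Inf)", {
  expect_equal(dapsa_score(0, 0, 0, 0, 0), 0)
  expect_equal(dapsa_score(2, 1, 3.0, 4.0, 0.4), 10.4)
  expect_error(dapsa_score(-1, 0, 0, 0, 0), "non-negative")
  expect_error(dapsa_score(0, 0, 12, 0, 0), "0-10")

  expect_equal(as.character(dapsa_category(4.0)), "REM")
  expect_equal(as.character(dapsa_category(14.0)), "LDA")
  expect_equal(as.character(dapsa_category(28.0)), "MDA")
  expect_equal(as.character(dapsa_category(28.01)), "HDA")
  expect_true(dapsa_lda_met(10.4))
  expect_true(dapsa_lda_met(4))  # remission is within the LDA target

  # bands partition: every score falls in exactly one band
  set.seed(16)
  sc <- c(0, runif(500, 0, 60), 4, 14, 28)
  expect_false(anyNA(dapsa_category(sc)))
  expect_error(dapsa_category(-0.1), "non-negative")
})

test_that("group assignment derives SDL and TNFi membership", {
  pats <- data.frame(patient_id = c("P1", "P2", "P3"),
                     dapsa_t0 = c(10, 10, NA),
                     dapsa_t5 = c(12, 20, 5),
                     tnfi_throughout = c(TRUE, FALSE, TRUE))
  expect_warning(g <- assign_groups(pats), "excluded")
  expect_equal(g$patient_id, c("P1", "P2"))
  expect_equal(g$sdl, c(TRUE, FALSE))
  expect_equal(g$tnfi, c(TRUE, FALSE))
})

test_that("uncorrected Pearson chi-square reproduces textbook values", {
  r1 <- progression_chisq(rbind(c(12, 39), c(25, 35)))
  expect_equal(r1$statistic, 4.081, tolerance = 1e-3)
  expect_equal(round(r1$p_value, 3), 0.043)
  r2 <- progression_chisq(rbind(c(8, 18), c(29, 56)))
  expect_equal(round(r2$p_value, 3), 0.751)
  r3 <- progression_chisq(rbind(c(15, 14), c(36, 34)))
  expect_equal(round(r3$p_value, 3), 0.979)

  # identical rows: no association at all
  r4 <- progression_chisq(rbind(c(10, 20), c(10, 20)))
  expect_equal(r4$statistic, 0)
  expect_equal(r4$p_value, 1)
  # empty margin: not available
  expect_true(is.na(progression_chisq(rbind(c(0, 0), c(5, 5)))$p_value))
})

test_that("chi-square p agrees with a conditional permutation oracle", {
  set.seed(17)
  # the residual chi-square approximation error at cell counts of this
  # order stays below 0.04 (checked by hypergeometric enumeration), so the
  # comparison allows it on top of the Monte-Carlo noise
  for (i in 1:5) {
    tab <- matrix(rpois(4, 60) + 10, 2, 2)
    p_chi <- progression_chisq(tab)$p_value
    perm <- permutation_chisq_p(tab, n_perm = 2000)
    expect_lt(abs(p_chi - perm$p_value), 3 * perm$mc_se + 0.04)
  }
})

make_group_fixture <- function(n_in, n_out, deltas_in, deltas_out,
                               prog_in, prog_out, kind = "erosion") {
  dyn <- data.frame(
    lesion_id = sprintf("L%03d", seq_len(n_in + n_out)),
    patient_id = rep(c("Pin", "Pout"), c(n_in, n_out)),
    kind = kind,
    delta_mm3 = c(deltas_in, deltas_out),
    is_new = FALSE)
  dyn$category <- factor(
    c(rep(c("progression", "stable"), c(prog_in, n_in - prog_in)),
      rep(c("progression", "stable"), c(prog_out, n_out - prog_out))),
    levels = c("progression", "stable", "regression"))
  pats <- data.frame(patient_id = c("Pin", "Pout"),
                     dapsa_t0 = c(10, 20), dapsa_t5 = c(10, 20),
                     tnfi_throughout = FALSE)
  list(dynamics = dyn, patients = assign_groups(pats))
}

test_that("lesion-level progression comparison rebuilds the printed table shape", {
  fx <- make_group_fixture(51, 60, rnorm(51, 0.5, 1.6), rnorm(60, 0.7, 1.4),
                           prog_in = 12, prog_out = 25)
  gc <- compare_progression_counts(fx$dynamics, fx$patients, "erosion", "sdl")
  expect_equal(unname(gc$table[1, ]), c(12, 39))
  expect_equal(unname(gc$table[2, ]), c(25, 35))
  expect_equal(round(gc$p_value, 3), 0.043)
  expect_equal(round(100 * gc$proportion_in, 1), 23.5)
  expect_equal(round(100 * gc$proportion_out, 1), 41.7)
})

test_that("mean-delta comparison gates on normality and handles degeneracy", {
  set.seed(18)
  fx <- make_group_fixture(40, 59, rnorm(40, 0.3, 0.7), rnorm(59, 0.6, 0.8),
                           prog_in = 17, prog_out = 33, kind = "enthesiophyte")
  gd <- compare_mean_deltas(fx$dynamics, fx$patients, "enthesiophyte", "sdl")
  expect_equal(gd$n_in, 40)
  expect_equal(gd$n_out, 59)
  expect_true(gd$p_value >= 0 && gd$p_value <= 1)

  # identical groups: no difference
  fx2 <- make_group_fixture(10, 10, 1:10 / 10, 1:10 / 10, 3, 3)
  gd2 <- compare_mean_deltas(fx2$dynamics, fx2$patients, "erosion", "sdl")
  expect_equal(gd2$p_value, 1)

  # degenerate variance falls back to the rank test
  fx3 <- make_group_fixture(10, 10, rep(0.2, 10), 1:10 / 10, 3, 3)
  gd3 <- compare_mean_deltas(fx3$dynamics, fx3$patients, "erosion", "sdl")
  expect_equal(gd3$test, "wilcoxon")
})

test_that("two-group test keeps its nominal type-I error under the null", {
  set.seed(19)
  rejections <- 0L
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    a <- rnorm(40, 0.5, 1)
    b <- rnorm(59, 0.5, 1)
    p <- pqctlong:::two_group_test(a, b)$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  # 3 binomial SDs around 5%
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("paired change test gates on normality of the differences", {
  expect_equal(paired_change_test(1:10, 1:10)$p_value, 1)
  expect_true(paired_change_test(1:10, 1:10)$all_zero)

  # antisymmetric differences: perfectly balanced, no change detectable
  t0 <- rep(5, 6)
  t5 <- 5 + c(-3, -2, -1, 1, 2, 3)
  expect_equal(paired_change_test(t0, t5)$p_value, 1, tolerance = 1e-9)

  # a mean shift of the study's size (0.6 mm^3 against SD 1.5 at n = 111,
  # noncentrality ~4.0) is detected at the 0.001 level with the power the
  # noncentral-t oracle predicts (~0.74); at the 0.05 level essentially
  # always
  set.seed(22)
  p_vals <- vapply(1:60, function(i) {
    d <- rnorm(111, 0.6, 1.5)
    paired_change_test(rep(4, 111), 4 + d)$p_value
  }, 0)
  power_oracle <- 1 - pt(qt(0.9995, 110), 110, ncp = 0.6 / (1.5 / sqrt(111)))
  expect_lt(abs(mean(p_vals < 0.001) - power_oracle),
            3 * sqrt(power_oracle * (1 - power_oracle) / 60))
  expect_gte(mean(p_vals < 0.05), 0.95)
  expect_error(paired_change_test(1:2, 2:3), "at least 3")
})

test_that("study report is internally consistent on simulated data", {
  sim <- simulate_cohort(cohort_spec(seed = 5))
  dyn <- lesion_dynamics(sim$lesions)
  pats <- assign_groups(sim$patients)
  rep_ <- build_report(dyn, pats)

  # counts: baseline + new = follow-up; totals partition across categories
  tot <- rep_$counts[rep_$counts$compartment == "total", ]
  expect_equal(tot$n_baseline + tot$n_new, tot$n_followup)
  s <- rep_$dynamics_summary
  for (kd in unique(s$kind))
    expect_equal(sum(s$n[s$kind == kd]), s$n_total[s$kind == kd][1])
  # group tables preserve the lesion-level denominators
  gcs <- rep_$group_counts
  for (i in seq_len(nrow(gcs))) {
    expect_equal(gcs$n_in[i] + gcs$n_out[i],
                 sum(dyn$kind == gcs$kind[i]))
  }
  # per-kind volumes carry a paired test result
  expect_true(all(rep_$volumes$p_value >= 0 & rep_$volumes$p_value <= 1))
})
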