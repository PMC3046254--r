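test_that("one-way ANOVA matches brute-force oracles", {
  a <- oneway_anova(c(1, 2, 3), c(2, 3, 4))
  expect_equal(a$F, oracle_anova_F(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)
  expect_equal(a$F, oracle_pooled_t2(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)
  expect_equal(a$df_num, 1L)
  expect_equal(a$df_den, 4L)
  # day-4 design sizes: 16 vs 17 -> df_den = 31
  set.seed(5)
  a2 <- oneway_anova(rnorm(16), rnorm(17))
  expect_equal(a2$df_den, 31L)
})

test_that("degenerate and invalid ANOVA inputs behave as specified", {
  a <- oneway_anova(c(2, 2, 2), c(2, 2, 2))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_error(oneway_anova(1, c(1, 2)), "at least two")
})

test_that("percent reduction is scale invariant and validated", {
  expect_equal(percent_reduction(10, 8), 20)
  expect_equal(percent_reduction(10 * 3.7, 8 * 3.7), 20, tolerance = 1e-12)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("per-1000 and log-odds conversions are inverse", {
  b <- 0.045
  lo <- per1000_to_logodds(-11.8, b)
  expect_equal(logodds_to_per1000(lo, b), -11.8, tolerance = 1e-10)
  expect_equal(per1000_to_logodds(0, b), 0)
})

test_that("compare_measurements reports the strongest-effect ordering", {
  meas <- rbind(
    measure_cohort(3, "control", shape_simplification = 0, seed = 10),
    measure_cohort(3, "immobilised", shape_simplification = 1, seed = 40)
  )
  cmp <- compare_measurements(meas)
  expect_equal(nrow(cmp), 12)
  expect_named(cmp, c("measurement", "mean_control", "mean_treated",
                      "percent_reduction", "F", "df_num", "df_den", "p"))
  red <- function(m) cmp$percent_reduction[cmp$measurement == m]
  # fossa-width reduction exceeds condyle-width reduction on both planes
  expect_gt(red("vii"), red("vi"))
  expect_gt(red("x"), red("ix"))
  expect_error(compare_measurements(meas[meas$treatment == "control", ]),
               "control")
})

test_that("binomial GLMM fits the nested design and converts effects", {
  tab <- generate_proliferation_counts(count_sim_params(seed = 21))
  g <- fit_binomial_glmm(tab)
  expect_s3_class(g, "glmm_result")
  expect_true(is.finite(g$effect_logodds))
  expect_gt(g$se, 0)
  expect_equal(g$df_t, 4L)
  expect_equal(g$effect_per_1000,
               logodds_to_per1000(g$effect_logodds, g$baseline),
               tolerance = 1e-12)
  expect_named(g$varcomp, c("individual", "section"))
  expect_true(is.logical(g$converged))
})

test_that("GLMM preconditions are enforced", {
  tab <- generate_proliferation_counts(count_sim_params(seed = 3))
  one <- tab[tab$individual_id %in% c("control_01", "immobilised_01"), ]
  expect_error(fit_binomial_glmm(one), "two individuals")
  bad <- tab; bad$n_pos[1] <- bad$n_total[1] + 5L
  expect_error(fit_binomial_glmm(bad), "invalid counts")
  expect_error(fit_binomial_glmm(tab[, 1:4]), "columns")
})
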