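test_that("count table matches the nested design layout", {
  p <- count_sim_params(n_individuals = 3, sections = 2, planes = 2,
                        seed = 8)
  tab <- generate_proliferation_counts(p)
  expect_equal(nrow(tab), 2 * 3 * 2 * 2 * 5)
  expect_named(tab, c("individual_id", "treatment", "section_id", "plane",
                      "region", "n_total", "n_pos"))
  expect_setequal(unique(tab$treatment), c("control", "immobilised"))
  expect_setequal(unique(tab$region), 1:5)
  expect_true(all(tab$n_pos >= 0 & tab$n_pos <= tab$n_total))
  expect_true(all(tab$n_total >= 1))
})

test_that("count generation is seed-deterministic", {
  p <- count_sim_params(seed = 123)
  expect_identical(generate_proliferation_counts(p),
                   generate_proliferation_counts(p))
  p2 <- count_sim_params(seed = 124)
  expect_false(identical(generate_proliferation_counts(p),
                         generate_proliferation_counts(p2)))
})

test_that("a strong negative effect lowers the immobilised-arm rate", {
  p <- count_sim_params(n_individuals = 10, effect = -2,
                        effect_scale = "log_odds", seed = 55)
  tab <- generate_proliferation_counts(p)
  rate <- tapply(tab$n_pos, tab$treatment, sum) /
    tapply(tab$n_total, tab$treatment, sum)
  expect_lt(rate[["immobilised"]], rate[["control"]])
})

test_that("count_sim_params validates its design", {
  expect_error(count_sim_params(baseline = 0))
  expect_error(count_sim_params(effect_scale = "percent"))
  expect_error(count_sim_params(n_individuals = 0))
})
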