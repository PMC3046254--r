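test_that("default muscle table has unit directions and valid groups", {
  tab <- default_muscle_table()
  expect_equal(nrow(tab), 4)
  expect_equal(sqrt(tab$dx^2 + tab$dz^2), rep(1, 4), tolerance = 1e-12)
  expect_setequal(unique(tab$group), c("flexor_set", "extensor_set"))
  expect_true(all(tab$magnitude_uN > 0))
})

test_that("contraction regimes activate only their muscle group", {
  tab <- default_muscle_table()
  lf <- build_load_case(tab, "flexion")
  le <- build_load_case(tab, "extension")
  expect_equal(length(lf$muscles), 2)
  expect_true(all(grepl("^flexor", vapply(lf$muscles, `[[`, "", "name"))))
  expect_true(all(grepl("^extensor", vapply(le$muscles, `[[`, "", "name"))))
  expect_equal(lf$temporal, "ramped_cycle")
  expect_equal(lf$scale, 1)
  expect_equal(lf$total_uN, sum(tab$magnitude_uN[tab$group == "flexor_set"]))
})

test_that("paralysis applies all muscles continuously at reduced force", {
  tab <- default_muscle_table()
  lp <- build_load_case(tab, "paralysis")
  expect_equal(length(lp$muscles), nrow(tab))
  expect_equal(lp$temporal, "constant")
  expect_equal(lp$scale, 0.75)
})

test_that("muscle table validation rejects malformed fixtures", {
  tab <- default_muscle_table()
  bad <- tab; bad$dx[1] <- 5
  expect_error(build_load_case(bad, "flexion"), "unit vectors")
  bad2 <- tab; bad2$magnitude_uN[2] <- 0
  expect_error(build_load_case(bad2, "flexion"), "positive")
  bad3 <- tab; bad3$group[1] <- "other"
  expect_error(build_load_case(bad3, "flexion"), "group")
  only_flex <- tab[tab$group == "flexor_set", ]
  expect_error(build_load_case(only_flex, "extension"), "no muscles")
})

test_that("muscle table CSV round trip preserves the fixture", {
  tab <- default_muscle_table()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_muscle_table(tab, path)
  back <- read_muscle_table(path)
  expect_equal(back, tab, tolerance = 1e-12)
  # missing columns rejected
  utils::write.csv(tab[, 1:3], path, row.names = FALSE)
  expect_error(read_muscle_table(path), "columns")
})
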