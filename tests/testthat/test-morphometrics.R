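test_that("segmentation splits the volume into disjoint rudiments", {
  vol <- cached_phantom()
  seg <- segment_rudiments(vol)
  expect_false(any(seg$femur & seg$tibiotarsus))
  expect_false(any(seg$femur & seg$fibula))
  expect_false(any(seg$tibiotarsus & seg$fibula))
  expect_identical(seg$femur | seg$tibiotarsus | seg$fibula, vol$voxels)
  expect_equal(seg$gap_voxels * vol$voxel_size,
               unname(vol$ground_truth["iii"]))
})

test_that("section planes are located with the expected axes", {
  sections <- locate_section_planes(cached_phantom())
  expect_named(sections, c("midline", "ventral", "epiphyseal"))
  expect_equal(sections$midline$axis, "y")
  expect_equal(sections$ventral$axis, "y")
  expect_equal(sections$epiphyseal$axis, "z")
  expect_lt(sections$ventral$index, sections$midline$index)
})

test_that("measurements on the default phantom recover ground truth exactly", {
  vol <- cached_phantom()
  m <- measure_knee(vol)
  expect_equal(c(m), vol$ground_truth, tolerance = 1e-12)
})

test_that("simplified phantom is measured exactly too", {
  vol <- generate_joint_phantom(phantom_params(shape_simplification = 1))
  m <- measure_knee(vol)
  expect_equal(c(m), vol$ground_truth, tolerance = 1e-12)
})

test_that("measure_cohort returns one row per specimen and measurement", {
  tab <- measure_cohort(2, "control", seed = 7)
  expect_equal(nrow(tab), 2 * 12)
  expect_named(tab, c("specimen", "treatment", "measurement", "length_mm",
                      "ground_truth_mm"))
  expect_equal(unique(tab$treatment), "control")
  expect_equal(length(unique(tab$specimen)), 2)
})
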