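test_that("phantom_params validates inputs", {
  expect_s3_class(phantom_params(), "phantom_params")
  expect_error(phantom_params(tt_width = -1), "positive length")
  expect_error(phantom_params(shape_simplification = 1.5), "\\[0, 1\\]")
  expect_error(phantom_params(ventral_slab_frac = 0.9), "ventral_slab_frac")
  # zero interzone gap is allowed (touching rudiments)
  expect_s3_class(phantom_params(interzone_gap = 0), "phantom_params")
})

test_that("effective dimensions shrink with shape_simplification", {
  p0 <- phantom_params(shape_simplification = 0)
  p1 <- phantom_params(shape_simplification = 1)
  e0 <- effective_phantom_dims(p0)
  e1 <- effective_phantom_dims(p1)
  expect_equal(e0$fossa_width_mid, p0$fossa_width_mid)
  expect_equal(e1$fossa_width_mid, p1$fossa_width_mid * (1 - 0.43))
  expect_lt(e1$condyle_height_lat, e0$condyle_height_lat)
  expect_lt(e1$interzone_gap, e0$interzone_gap)
})

test_that("generated phantom carries exact voxel-snapped ground truth", {
  vol <- cached_phantom()
  expect_s3_class(vol, "shape_volume")
  expect_named(vol$ground_truth,
               c("i", "ii", "iii", "iv", "iv-b", "v",
                 "vi", "vii", "iix", "ix", "x", "xi"))
  # every ground-truth length is a whole number of voxels
  expect_equal(vol$ground_truth / vol$voxel_size,
               round(vol$ground_truth / vol$voxel_size))
  expect_true(any(vol$voxels))
})

test_that("random phantom parameters are seed-deterministic", {
  a <- random_phantom_params(42)
  b <- random_phantom_params(42)
  c <- random_phantom_params(43)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(a$tt_width, c$tt_width))
})

test_that("shape volume NIfTI round trip preserves voxels and ground truth", {
  vol <- generate_joint_phantom(phantom_params(voxel_size = 0.02))
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_shape_volume(vol, path)
  back <- read_shape_volume(path)
  expect_identical(back$voxels, vol$voxels)
  # NIfTI stores pixdim as float32
  expect_equal(back$voxel_size, vol$voxel_size, tolerance = 1e-6)
  expect_equal(unlist(back$ground_truth[names(vol$ground_truth)]),
               vol$ground_truth, tolerance = 1e-12)
})
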