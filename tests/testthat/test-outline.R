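test_that("outline extraction returns a closed sub-voxel polygon", {
  vol <- cached_phantom()
  o <- extract_outline(vol)
  expect_s3_class(o, "joint_outline")
  expect_true(nrow(o$polygon) > 10)
  # open ring: last vertex is not a duplicate of the first
  n <- nrow(o$polygon)
  expect_false(all(abs(o$polygon[1, ] - o$polygon[n, ]) < 1e-12))
  expect_gt(outline_perimeter(o), 0)
  expect_false(is.null(o$anchors))
  expect_named(o$anchors, c("medial_line", "lateral_line", "fossa_mid"))
  # polygon area approximates the femoral slice area
  sl <- segment_rudiments(vol)$femur[, o$plane$index, ]
  slice_area <- sum(sl) * vol$voxel_size^2
  poly_area <- abs(sum(o$polygon[, 1] *
                         o$polygon[c(2:n, 1), 2] -
                         o$polygon[c(2:n, 1), 1] * o$polygon[, 2]) / 2)
  expect_lt(abs(poly_area - slice_area) / slice_area, 0.15)
})

test_that("alignment is rigid and idempotent", {
  o <- extract_outline(cached_phantom())
  a1 <- align_outline(o)
  # rigid: perimeter preserved
  expect_equal(outline_perimeter(a1), outline_perimeter(o),
               tolerance = 1e-10)
  expect_equal(unname(a1$anchors$fossa_mid), c(0, 0))
  # idempotent: applying the alignment again changes nothing
  a2 <- align_outline(a1)
  expect_lt(max(abs(a2$polygon - a1$polygon)), 1e-6)
})

test_that("align_outline requires anatomical anchors", {
  o <- extract_outline(cached_phantom())
  o$anchors <- NULL
  expect_error(align_outline(o), "anchors")
})

test_that("overlay reports a narrower fossa for the simplified phantom", {
  o_ctrl <- extract_outline(cached_phantom())
  o_simp <- extract_outline(
    generate_joint_phantom(phantom_params(shape_simplification = 1)))
  ov <- overlay_outlines(list(o_ctrl, o_simp))
  expect_equal(nrow(ov$report), 2)
  expect_false(any(is.na(ov$report$fossa_width)))
  expect_lt(ov$report$fossa_width[2], ov$report$fossa_width[1])
  # both aligned outlines share the common frame origin
  for (a in ov$aligned) {
    expect_equal(unname(a$anchors$fossa_mid), c(0, 0))
  }
  expect_error(overlay_outlines(list(o_ctrl)), "at least two")
})
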