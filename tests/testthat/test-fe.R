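test_that("material and time-scheme constructors validate", {
  expect_error(poroelastic_material(E = -1), "E > 0")
  expect_error(poroelastic_material(E = 1, nu = 0.5), "nu < 0.5")
  mat <- poroelastic_material(E = 1, nu = 0.3, k = 300)
  expect_equal(mat$M_conf, mat$lambda + 2 * mat$G, tolerance = 1e-12)
  expect_equal(mat$k_int, 0.3, tolerance = 1e-12)
  mm <- material_map()
  expect_named(mm, c("cartilage", "interzone"))
  # default invariant: interzone softer and more permeable than cartilage
  expect_lt(mm$interzone$E, mm$cartilage$E)
  expect_gt(mm$interzone$k, mm$cartilage$k)
  expect_equal(mm$interzone$k / mm$cartilage$k, 10, tolerance = 1e-12)
  expect_error(time_scheme(-1, 10))
  expect_error(time_scheme(1, 10, snapshots = 2))
})

test_that("solver rejects missing materials and unknown node sets", {
  m <- rect_mesh(2, 2, 1, 1, label = "bone")
  expect_error(
    solve_poroelastic(m, material_map(), NULL, time_scheme(1, 1),
                      constraints = list(fix = "left", drained = "right")),
    "no material")
  m2 <- rect_mesh(2, 2, 1, 1)
  expect_error(
    solve_poroelastic(m2, material_map(), NULL, time_scheme(1, 1),
                      constraints = list(fix = "nope", drained = "right")),
    "unknown node set")
})

test_that("zero load yields the zero solution", {
  m <- rect_mesh(3, 3, 1, 1)
  sol <- solve_poroelastic(m, material_map(), NULL, time_scheme(1, 2),
                           constraints = list(fix = "bottom",
                                              drained = "external"))
  snap <- sol$snapshots[[1]]
  expect_equal(max(abs(snap$u)), 0, tolerance = 1e-14)
  expect_equal(max(abs(snap$p)), 0, tolerance = 1e-14)
  expect_equal(max(snap$elem$vm), 0, tolerance = 1e-14)
})

test_that("sealed constraint removes nodes from the drained set", {
  m <- rect_mesh(4, 8, 0.1, 1)
  mats <- material_map(cartilage = poroelastic_material(E = 1, nu = 0.3,
                                                        k = 10))
  load <- list(nodes = "top", traction = c(0, -5))
  sch <- time_scheme(1, 5)
  base <- solve_poroelastic(m, mats, load, sch,
    constraints = list(fix_x = c("left", "right"), fix_z = "bottom",
                       drained = "top"))
  # draining top+bottom but sealing bottom must reproduce drained-top only
  sealed <- solve_poroelastic(m, mats, load, sch,
    constraints = list(fix_x = c("left", "right"), fix_z = "bottom",
                       drained = c("top", "bottom"), sealed = "bottom"))
  expect_equal(sealed$snapshots[[1]]$p, base$snapshots[[1]]$p,
               tolerance = 1e-12)
  # without sealing, the extra drained boundary changes the field
  both <- solve_poroelastic(m, mats, load, sch,
    constraints = list(fix_x = c("left", "right"), fix_z = "bottom",
                       drained = c("top", "bottom")))
  expect_gt(max(abs(both$snapshots[[1]]$p - base$snapshots[[1]]$p)), 1e-6)
})

test_that("snapshots are taken at the requested times", {
  m <- rect_mesh(2, 2, 1, 1)
  sol <- solve_poroelastic(m, material_map(), NULL,
                           time_scheme(1, 10, snapshots = c(0.3, 1)),
                           constraints = list(fix = "bottom",
                                              drained = "external"))
  expect_equal(length(sol$snapshots), 2)
  expect_equal(sol$snapshots[[1]]$t, 0.3, tolerance = 1e-12)
  expect_equal(sol$snapshots[[2]]$t, 1.0, tolerance = 1e-12)
})

test_that("load ramp scales the applied force factor", {
  m <- rect_mesh(4, 4, 1, 1)
  load <- list(nodes = "top", traction = c(0, -2))
  sol <- solve_poroelastic(m, material_map(), load,
                           time_scheme(1, 4, ramp = 1,
                                       snapshots = c(0.25, 1)),
                           constraints = list(fix = "bottom",
                                              drained = seq_len(25)))
  expect_equal(sol$snapshots[[1]]$load_factor, 0.25, tolerance = 1e-12)
  expect_equal(sol$snapshots[[2]]$load_factor, 1, tolerance = 1e-12)
  # drained linear elasticity: response is proportional to the load factor
  expect_equal(sol$snapshots[[1]]$u * 4, sol$snapshots[[2]]$u,
               tolerance = 1e-8)
})
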