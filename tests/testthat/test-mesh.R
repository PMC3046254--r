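test_that("rect_mesh builds the expected structured lattice", {
  m <- rect_mesh(4, 5, 2, 2.5)
  expect_equal(nrow(m$nodes), 5 * 6)
  expect_equal(nrow(m$tri), 2 * 4 * 5)
  g <- tri_geometry(m)
  expect_equal(sum(g$area), 2 * 2.5, tolerance = 1e-12)
  expect_equal(mesh_min_angle(m), 45, tolerance = 1e-8)
  expect_equal(length(m$node_sets$left), 6)
  expect_equal(length(m$node_sets$top), 5)
})

test_that("shape-function gradients reproduce a linear field exactly", {
  m <- rect_mesh(3, 3, 1, 1)
  f <- 2 + 3 * m$nodes[, 1] - 5 * m$nodes[, 2]
  g <- tri_geometry(m)
  fe <- cbind(f[m$tri[, 1]], f[m$tri[, 2]], f[m$tri[, 3]])
  expect_equal(rowSums(g$b * fe), rep(3, nrow(m$tri)), tolerance = 1e-12)
  expect_equal(rowSums(g$c * fe), rep(-5, nrow(m$tri)), tolerance = 1e-12)
})

test_that("phantom_to_mesh provides labels, node sets and landmarks", {
  mesh <- cached_mesh()
  expect_s3_class(mesh, "joint_mesh")
  expect_setequal(unique(mesh$label), c("cartilage", "interzone"))
  expect_setequal(unique(mesh$rudiment), c("femur", "tibia", "interzone"))
  needed <- c("fix_femur", "fix_tibia", "flexor_lat", "flexor_med",
              "extensor_lat", "extensor_med", "capsule")
  expect_true(all(needed %in% names(mesh$node_sets)))
  for (s in needed) expect_gt(length(mesh$node_sets[[s]]), 0)
  # the capsule is the external margin of the interzone
  iz_nodes <- unique(as.vector(mesh$tri[mesh$rudiment == "interzone", ]))
  expect_true(all(mesh$node_sets$capsule %in% mesh$boundary$external))
  expect_true(all(mesh$node_sets$capsule %in% iz_nodes))
  expect_gte(mesh_min_angle(mesh), 45 - 1e-8)
  expect_true(is.finite(mesh$landmarks$fossa_floor_z))
  expect_true(is.finite(mesh$landmarks$fossa_mid_x))
  # fixed cuts sit at the extreme z of their rudiment
  expect_equal(min(mesh$nodes[mesh$node_sets$fix_tibia, 2]),
               min(mesh$nodes[, 2]))
  expect_equal(max(mesh$nodes[mesh$node_sets$fix_femur, 2]),
               max(mesh$nodes[, 2]))
})

test_that("meshing is deterministic for a given phantom", {
  m1 <- phantom_to_mesh(cached_phantom())
  m2 <- phantom_to_mesh(cached_phantom())
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tri, m2$tri)
  expect_identical(m1$node_sets, m2$node_sets)
})

test_that("write_vtk emits a consistent legacy unstructured grid", {
  m <- rect_mesh(2, 2, 1, 1)
  path <- tempfile(fileext = ".vtk")
  on.exit(unlink(path))
  write_vtk(m, path, point_data = list(p = seq_len(nrow(m$nodes))),
            cell_data = list(vm = seq_len(nrow(m$tri))))
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(paste("POINTS", nrow(m$nodes), "float"), txt,
                        fixed = TRUE)))
  expect_true(any(grepl(paste("CELLS", nrow(m$tri), 4 * nrow(m$tri)), txt,
                        fixed = TRUE)))
  expect_true(any(grepl("SCALARS vm float 1", txt, fixed = TRUE)))
})
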