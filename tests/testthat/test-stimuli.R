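test_that("probe_region requires a polygon or band", {
  expect_error(probe_region("x"), "polygon or a band")
  expect_s3_class(probe_region("x", band = list(mode = "mid", dist = 0.02)),
                  "probe_region")
})

test_that("sample_region computes area-weighted statistics", {
  m <- rect_mesh(4, 4, 1, 1)
  sol <- solve_poroelastic(m, material_map(),
                           list(nodes = "top", traction = c(0, -2)),
                           time_scheme(1, 2),
                           constraints = list(fix = "bottom",
                                              drained = "external"))
  whole <- probe_region("whole",
                        polygon = cbind(x = c(-1, 2, 2, -1),
                                        z = c(-1, -1, 2, 2)))
  out <- sample_region(sol, whole)
  el <- sol$snapshots[[length(sol$snapshots)]]$elem
  for (f in c("vm", "s1", "s2", "p", "qmag")) {
    expect_equal(out$mean[out$field == f],
                 sum(el$area * el[[f]]) / sum(el$area), tolerance = 1e-12)
    expect_equal(out$max[out$field == f], max(el[[f]]), tolerance = 1e-12)
  }
  empty <- probe_region("empty",
                        polygon = cbind(x = c(5, 6, 6, 5),
                                        z = c(5, 5, 6, 6)))
  expect_error(sample_region(sol, empty), "intersects no elements")
})

test_that("default probe regions cover the eight anatomical locations", {
  res <- cached_stimuli()
  regions <- default_probe_regions(res$mesh)
  expect_named(regions, c("fossa_adjacent", "dorsal_medial",
                          "ventral_medial", "dorsal_lateral",
                          "ventral_lateral", "patella_region",
                          "chondrogenous_layer", "intermediate_layer"))
})

test_that("region means match an independent brute-force computation", {
  res <- cached_stimuli()
  mesh <- res$mesh
  sol <- res$solutions$flex
  el <- sol$snapshots[[length(sol$snapshots)]]$elem
  ctr <- tri_centroids(mesh)
  # chondrogenous layer: interzone elements within 0.025 mm of an interface
  ip <- mesh$nodes[mesh$boundary$interface, , drop = FALSE]
  d <- vapply(seq_len(nrow(ctr)), function(i) {
    min(sqrt((ip[, 1] - ctr[i, 1])^2 + (ip[, 2] - ctr[i, 2])^2))
  }, numeric(1))
  idx <- which(mesh$label == "interzone" & d <= 0.025)
  expected <- sum(el$area[idx] * el$qmag[idx]) / sum(el$area[idx])
  regions <- default_probe_regions(mesh)
  got <- sample_region(sol, regions$chondrogenous_layer)
  expect_equal(got$mean[got$field == "qmag"], expected, tolerance = 1e-12)
  # and the intermediate layer is the complementary interzone mid-band
  idx_mid <- which(mesh$label == "interzone" & d > 0.025)
  got_mid <- sample_region(sol, regions$intermediate_layer)
  expect_equal(got_mid$mean[got_mid$field == "p"],
               sum(el$area[idx_mid] * el$p[idx_mid]) / sum(el$area[idx_mid]),
               tolerance = 1e-12)
})

test_that("dynamic amplitude is zero for identical or single-phase input", {
  res <- cached_stimuli()
  flex <- res$solutions$flex
  amp_same <- dynamic_amplitude(flex, flex)
  expect_equal(max(abs(as.matrix(amp_same))), 0)
  amp_null <- dynamic_amplitude(flex, NULL)
  expect_equal(max(abs(as.matrix(amp_null))), 0)
  amp <- dynamic_amplitude(flex, res$solutions$ext)
  expect_gt(max(amp$vm), 0)
})

test_that("stimulus summaries carry fractions, background and amplitude", {
  res <- cached_stimuli()
  s <- res$summaries$normal
  expect_s3_class(s, "stimulus_summary")
  expect_setequal(unique(s$table$phase), c("flex", "ext"))
  expect_true(all(s$compressive_fraction >= 0 &
                    s$compressive_fraction <= 1))
  expect_setequal(unique(s$background$field),
                  c("vm", "s1", "s2", "p", "qmag"))
  p <- res$summaries$paralysis
  expect_equal(max(abs(p$amplitude$amplitude)), 0)
})

test_that("compare_regimes validates matching region sets", {
  res <- cached_stimuli()
  s2 <- res$summaries$paralysis
  s2$regions <- s2$regions[-1]
  expect_error(compare_regimes(res$summaries$normal, s2),
               "region sets differ")
  rep <- res$report
  expect_s3_class(rep, "comparison_report")
  expect_equal(length(unique(rep$ratios$region)), 8)
  expect_true(all(vapply(rep$flags, is.logical, logical(1))))
})
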