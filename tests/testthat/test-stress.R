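test_that("Von Mises satisfies the canonical identities", {
  # uniaxial sigma (true 2D state, s33 = 0) -> vm = |sigma|
  expect_equal(von_mises(7, 0, 0, s33 = 0), 7, tolerance = 1e-14)
  # hydrostatic -> 0
  expect_equal(von_mises(-3, -3, 0, s33 = -3), 0, tolerance = 1e-14)
  # pure shear tau -> sqrt(3) tau
  expect_equal(von_mises(0, 0, 2.5, s33 = 0), sqrt(3) * 2.5,
               tolerance = 1e-14)
  # default plane-strain s33 = nu (s11 + s22)
  expect_equal(von_mises(1, 2, 0.5, nu = 0.3),
               von_mises(1, 2, 0.5, s33 = 0.3 * 3), tolerance = 1e-14)
})

test_that("principal stresses match the eigen oracle and are invariant", {
  set.seed(11)
  s11 <- rnorm(500); s22 <- rnorm(500); s12 <- rnorm(500)
  pr <- principal_stresses(s11, s22, s12)
  or <- oracle_principal_eigen(s11, s22, s12)
  expect_equal(unname(pr), unname(or), tolerance = 1e-12)
  # rotation invariance of the principal values
  th <- runif(500, 0, pi)
  ct <- cos(th); st <- sin(th)
  r11 <- ct^2 * s11 + st^2 * s22 + 2 * ct * st * s12
  r22 <- st^2 * s11 + ct^2 * s22 - 2 * ct * st * s12
  r12 <- (s22 - s11) * ct * st + (ct^2 - st^2) * s12
  expect_equal(principal_stresses(r11, r22, r12), pr, tolerance = 1e-10)
})

test_that("Darcy flux is exact for constant and linear pressure fields", {
  m <- rect_mesh(5, 5, 1, 1)
  q0 <- darcy_flux(rep(4.2, nrow(m$nodes)), m, 1e-2)
  expect_equal(max(abs(q0)), 0, tolerance = 1e-14)
  p <- 1 + 2 * m$nodes[, 1] - 3 * m$nodes[, 2]
  q <- darcy_flux(p, m, 1e-2)
  expect_equal(unname(q[, 1]), rep(-1e-2 * 2, nrow(m$tri)),
               tolerance = 1e-12)
  expect_equal(unname(q[, 2]), rep(1e-2 * 3, nrow(m$tri)),
               tolerance = 1e-12)
})
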