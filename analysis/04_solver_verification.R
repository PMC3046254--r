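#!/usr/bin/env Rscript
# Solver verification suite: elastic patch test (prescribed linear
# displacement field, exact constant-stress recovery) and the Terzaghi 1D
# consolidation benchmark against the analytic series, with a refinement
# sweep. Writes results/verification.json.
#
# Usage: Rscript analysis/04_solver_verification.R [--out DIR]

library(jointmorph)

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
out <- get_opt("--out", "results")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## patch test -----------------------------------------------------------------
m <- rect_mesh(4, 4, 1, 1)
E <- 2.3; nu <- 0.27
mats <- material_map(cartilage = poroelastic_material(E = E, nu = nu,
                                                      alpha = 1, k = 1e-2))
Amat <- matrix(c(0.01, 0.003, 0.003, -0.004), 2, 2)
bn <- m$boundary$external
uv <- m$nodes[bn, ] %*% t(Amat)
presc <- data.frame(node = rep(bn, 2), dof = rep(c(1L, 2L), each = length(bn)),
                    value = c(uv[, 1], uv[, 2]))
sol <- solve_poroelastic(m, mats, NULL, time_scheme(1, 1),
                         constraints = list(prescribed = presc,
                                            drained = seq_len(nrow(m$nodes))))
el <- sol$snapshots[[1]]$elem
G <- E / (2 * (1 + nu)); lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
exact <- c(sxx = (lam + 2 * G) * 0.01 + lam * (-0.004),
           szz = lam * 0.01 + (lam + 2 * G) * (-0.004),
           sxz = G * 0.006)
patch_err <- max(abs(el$sxx - exact["sxx"]), abs(el$szz - exact["szz"]),
                 abs(el$sxz - exact["sxz"])) / max(abs(exact))

## Terzaghi column ------------------------------------------------------------
terzaghi_series <- function(zt, Tv, n_terms = 200) {
  s <- 0
  for (mi in 0:n_terms) {
    M <- (2 * mi + 1) * pi / 2
    s <- s + 4 / (pi * (2 * mi + 1)) * sin(M * zt) * exp(-M^2 * Tv)
  }
  s
}
terz_err <- function(nz, nx, nsteps) {
  H <- 1; p0 <- 10
  mm <- rect_mesh(nx, nz, 0.1, H)
  mat <- material_map(cartilage = poroelastic_material(E = 1, nu = 0.3,
                                                       alpha = 1, k = 1e-2))
  cv <- mat$cartilage$k_int * mat$cartilage$M_conf
  Ts <- c(0.1, 0.3, 0.5)
  sch <- time_scheme(0.5 * H^2 / cv, nsteps, snapshots = Ts * H^2 / cv)
  sol <- solve_poroelastic(mm, mat, list(nodes = "top", traction = c(0, -p0)),
                           sch,
                           constraints = list(fix_x = c("left", "right"),
                                              fix_z = "bottom",
                                              drained = "top"))
  sapply(seq_along(Ts), function(k) {
    zt <- 1 - mm$nodes[, 2] / H
    max(abs(sol$snapshots[[k]]$p - p0 * terzaghi_series(zt, Ts[k]))) / p0
  })
}
e20 <- terz_err(20, 2, 75)
e40 <- terz_err(40, 4, 150)
e80 <- terz_err(80, 8, 300)

report <- list(
  patch_test_relative_error = patch_err,
  terzaghi_time_factors = c(0.1, 0.3, 0.5),
  terzaghi_max_rel_error = list(`20x2` = e20, `40x4` = e40, `80x8` = e80),
  refinement_monotone = max(e20) > max(e40) && max(e40) > max(e80)
)
jsonlite::write_json(report, file.path(out, "verification.json"),
                     auto_unbox = TRUE, digits = NA)
cat("patch test relative error:", signif(patch_err, 3), "\n")
cat("terzaghi max rel errors: 20x2", signif(max(e20), 3),
    "| 40x4", signif(max(e40), 3), "| 80x8", signif(max(e80), 3), "\n")
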