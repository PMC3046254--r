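#' Von Mises stress
#'
#' Deviatoric second-invariant (distortional) stress measure,
#' \eqn{\sqrt{((s11-s22)^2+(s22-s33)^2+(s33-s11)^2)/2 + 3 s12^2}}.
#' Under plane strain the out-of-plane component defaults to the elastic
#' value \eqn{s33 = \nu (s11 + s22)}; pass `s33` explicitly to override
#' (e.g. 0 for a genuinely 2D stress state).
#'
#' @param s11,s22,s12 in-plane stress components (kPa), vectorised.
#' @param s33 out-of-plane normal stress; either a vector or NULL to use the
#'   plane-strain elastic value with `nu`.
#' @param nu Poisson ratio used when `s33` is NULL.
#' @return vector of Von Mises stresses (kPa), non-negative.
#' @export
von_mises <- function(s11, s22, s12, s33 = NULL, nu = 0.3) {
  if (is.null(s33)) s33 <- nu * (s11 + s22)
  sqrt(pmax(0, 0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
              3 * s12^2))
}

#' In-plane principal stresses
#'
#' Eigenvalues of the symmetric 2D stress tensor in closed form, sorted
#' descending (maximum = tension, minimum = compression). Rotation-invariant.
#'
#' @param s11,s22,s12 in-plane components (kPa), vectorised.
#' @return matrix with columns `s1 >= s2` (kPa).
#' @export
principal_stresses <- function(s11, s22, s12) {
  m <- (s11 + s22) / 2
  r <- sqrt(((s11 - s22) / 2)^2 + s12^2)
  cbind(s1 = m + r, s2 = m - r)
}

#' Darcy flux from a nodal pressure field
#'
#' Computes the element-wise Darcy flux \eqn{q = -k \nabla p} on linear
#' triangles: the pressure gradient is constant per element, so uniform
#' pressure gives exactly zero flux. `|q|` is the fluid velocity magnitude.
#'
#' @param p nodal pore pressure (kPa).
#' @param mesh a `joint_mesh`.
#' @param k per-element hydraulic permeability, internal units
#'   mm^2 kPa^-1 s^-1 (= mm^4 mN^-1 s^-1); recycled if scalar.
#' @return ne x 2 matrix of flux vectors (mm/s).
#' @export
darcy_flux <- function(p, mesh, k) {
  g <- tri_geometry(mesh)
  pe <- cbind(p[mesh$tri[, 1]], p[mesh$tri[, 2]], p[mesh$tri[, 3]])
  gx <- rowSums(g$b * pe)
  gz <- rowSums(g$c * pe)
  cbind(qx = -k * gx, qz = -k * gz)
}
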