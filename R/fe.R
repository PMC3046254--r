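#' Poroelastic material map
#'
#' Per-tissue linear Biot poroelastic constants. The default values are
#' configurable placeholders on the kPa scale of embryonic soft tissue — the
#' interzone is softer (E/10) and ten times more permeable than cartilage —
#' and are not measurements. The absolute permeability scale is set so that
#' the consolidation diffusion length sqrt(c_v t) at the mid-contraction
#' reporting time (0.25 s) is comparable to the joint-region half-depth
#' (~0.3 mm): c_v = k 1e-3 (lambda + 2G) gives k = 300 for cartilage. At that
#' scale the section is at mid-consolidation when reported, the regime in
#' which interstitial flow patterns are informative.
#'
#' @param ... named tissue entries, each created by [poroelastic_material()].
#' @return a `material_map` (named list).
#' @export
material_map <- function(...) {
  mats <- list(...)
  if (length(mats) == 0) {
    mats <- list(
      cartilage = poroelastic_material(E = 1.0, nu = 0.3, alpha = 1,
                                       k = 300),
      interzone = poroelastic_material(E = 0.1, nu = 0.3, alpha = 1,
                                       k = 3000)
    )
  }
  stopifnot(!is.null(names(mats)), all(nzchar(names(mats))))
  structure(mats, class = "material_map")
}

#' Single-tissue poroelastic constants
#'
#' @param E Young's modulus, kPa (> 0).
#' @param nu Poisson ratio, in [0, 0.5).
#' @param alpha Biot coefficient, in (0, 1].
#' @param k hydraulic permeability, mm^4 N^-1 s^-1 (> 0).
#' @return list of validated constants with derived plane-strain moduli:
#'   `G`, `lambda`, `M_conf` (confined modulus, kPa) and `k_int`
#'   (permeability in internal mm^4 mN^-1 s^-1 units).
#' @export
poroelastic_material <- function(E, nu = 0.3, alpha = 1, k = 1e-2) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, alpha > 0, alpha <= 1, k > 0)
  G <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  list(E = E, nu = nu, alpha = alpha, k = k,
       G = G, lambda = lambda, M_conf = lambda + 2 * G,
       k_int = k * 1e-3)
}

#' Time-integration scheme
#'
#' Backward-Euler stepping with a linear load ramp followed by a hold.
#' Snapshot times select which converged states are retained in the solution
#' (the nearest discrete step time is used).
#'
#' @param total total simulated time, s.
#' @param n_steps number of equal implicit steps (>= 1).
#' @param ramp time over which the load ramps linearly from 0 to full
#'   (0 = load applied instantaneously at the first step).
#' @param snapshots times (s) at which fields are reported; default end time.
#' @return a `time_scheme`.
#' @export
time_scheme <- function(total, n_steps, ramp = 0, snapshots = total) {
  stopifnot(total > 0, n_steps >= 1, ramp >= 0, ramp <= total,
            all(snapshots >= 0), all(snapshots <= total))
  structure(list(total = total, n_steps = as.integer(n_steps), ramp = ramp,
                 snapshots = snapshots), class = "time_scheme")
}

# expand node-set references ("fix_femur", "external", ...) to node indices
.resolve_nodes <- function(mesh, spec) {
  if (is.null(spec)) return(integer(0))
  if (is.character(spec)) {
    out <- integer(0)
    for (s in spec) {
      if (s %in% names(mesh$node_sets)) {
        out <- c(out, mesh$node_sets[[s]])
      } else if (s %in% names(mesh$boundary)) {
        out <- c(out, mesh$boundary[[s]])
      } else {
        stop("unknown node set '", s, "'")
      }
    }
    sort(unique(out))
  } else {
    sort(unique(as.integer(spec)))
  }
}

#' Solve quasi-static linear Biot poroelasticity
#'
#' u-p mixed formulation on linear triangles for both displacement and pore
#' pressure, with incompressible constituents (zero storage) and isotropic
#' permeability. Equal-order interpolation is stabilised by a pressure
#' Laplacian acting on the pressure increment (scale beta h^2 / (lambda+2G)),
#' which vanishes at steady state. Time integration is implicit backward
#' Euler (unconditionally stable). The discrete force balance is verified at
#' every retained snapshot: the norm of the equilibrium residual on free
#' displacement dofs must stay below `tol` times the applied load norm.
#'
#' @param mesh a `joint_mesh`.
#' @param materials a `material_map` with an entry per element label.
#' @param load a `load_case` (see [build_load_case()]) or NULL for no load.
#' @param scheme a `time_scheme`.
#' @param constraints list with `fix` (node sets / indices with u = 0),
#'   optional `fix_x`, `fix_z` (single-component rollers), optional
#'   `prescribed` (data.frame node, dof (1 = x, 2 = z), value in mm), and
#'   `drained` (node sets / indices with p = 0; default "external"), and
#'   optional `sealed` (node sets / indices removed from the drained set,
#'   i.e. impermeable boundary such as the joint capsule).
#' @param stab_beta dimensionless scale of the pressure-increment
#'   stabilisation term.
#' @param tol relative tolerance for the equilibrium check.
#' @return a `field_solution`: list(mesh, times, snapshots); each snapshot
#'   holds t, u (n x 2 mm), p (kPa), element table with stress components
#'   (kPa), Von Mises, principal stresses, Darcy flux (mm/s) and element
#'   label, plus the load factor at that time.
#' @export
solve_poroelastic <- function(mesh, materials, load, scheme,
                              constraints = list(fix = c("fix_femur",
                                                         "fix_tibia"),
                                                 drained = "external"),
                              stab_beta = 0.25, tol = 1e-8) {
  stopifnot(inherits(mesh, "joint_mesh"), inherits(scheme, "time_scheme"))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$tri)
  labs <- unique(mesh$label)
  miss <- setdiff(labs, names(materials))
  if (length(miss)) stop("no material for label(s): ",
                         paste(miss, collapse = ", "))
  g <- tri_geometry(mesh)
  matE <- lapply(c("G", "lambda", "alpha", "k_int", "M_conf", "nu"),
                 function(f) vapply(mesh$label,
                                    function(l) materials[[l]][[f]],
                                    numeric(1), USE.NAMES = FALSE))
  names(matE) <- c("G", "lambda", "alpha", "k_int", "M_conf", "nu")

  asm <- .assemble_biot(mesh, g, matE, stab_beta)
  ndof_u <- 2L * n

  # Dirichlet bookkeeping ----------------------------------------------------
  fix_nodes <- .resolve_nodes(mesh, constraints$fix)
  fixed_u <- c(2L * fix_nodes - 1L, 2L * fix_nodes)
  if (!is.null(constraints$fix_x)) {
    fixed_u <- c(fixed_u, 2L * .resolve_nodes(mesh, constraints$fix_x) - 1L)
  }
  if (!is.null(constraints$fix_z)) {
    fixed_u <- c(fixed_u, 2L * .resolve_nodes(mesh, constraints$fix_z))
  }
  presc_val <- numeric(0); presc_dof <- integer(0)
  if (!is.null(constraints$prescribed)) {
    pr <- constraints$prescribed
    presc_dof <- 2L * (pr$node - 1L) + pr$dof
    presc_val <- pr$value
    fixed_u <- c(fixed_u, presc_dof)
  }
  fixed_u <- sort(unique(fixed_u))
  drained <- .resolve_nodes(mesh,
                            if (is.null(constraints$drained)) "external"
                            else constraints$drained)
  if (!is.null(constraints$sealed)) {
    drained <- setdiff(drained, .resolve_nodes(mesh, constraints$sealed))
  }
  fixed_p <- ndof_u + drained
  fixed_all <- c(fixed_u, fixed_p)
  ndof <- ndof_u + n
  free <- setdiff(seq_len(ndof), fixed_all)
  if (length(free) == 0 && length(presc_dof) == 0) {
    stop("solve_poroelastic: no free degrees of freedom")
  }

  dt <- scheme$total / scheme$n_steps
  A <- rbind(cbind(asm$K, -asm$Q),
             cbind(Matrix::t(asm$Q), dt * asm$H + asm$S))
  x_fix <- numeric(ndof)
  if (length(presc_dof)) x_fix[presc_dof] <- presc_val
  A_ff <- A[free, free, drop = FALSE]
  A_fc <- A[free, fixed_all, drop = FALSE]
  fac <- Matrix::lu(A_ff)

  f_full <- .load_vector(mesh, load, n)
  times <- dt * seq_len(scheme$n_steps)
  snap_steps <- unique(pmax(1L, pmin(scheme$n_steps,
                                     round(scheme$snapshots / dt))))
  x <- numeric(ndof)
  snaps <- list()
  for (s in seq_len(scheme$n_steps)) {
    t_s <- times[s]
    fac_load <- if (scheme$ramp > 0) min(1, t_s / scheme$ramp) else 1
    rhs <- numeric(ndof)
    rhs[seq_len(ndof_u)] <- fac_load * f_full
    rhs[ndof_u + seq_len(n)] <-
      as.numeric(Matrix::t(asm$Q) %*% x[seq_len(ndof_u)]) +
      as.numeric(asm$S %*% x[ndof_u + seq_len(n)])
    x_new <- x_fix
    b_f <- rhs[free] - as.numeric(A_fc %*% x_fix[fixed_all])
    sol <- Matrix::solve(fac, b_f)
    if (any(!is.finite(sol))) {
      stop("solve_poroelastic: linear solver failed (singular system? ",
           "check constraints)")
    }
    x_new[free] <- as.numeric(sol)
    x <- x_new
    if (s %in% snap_steps) {
      snaps[[length(snaps) + 1L]] <-
        .postprocess(mesh, g, matE, x, t_s, fac_load, f_full, asm,
                     fixed_u, tol)
    }
  }
  structure(list(mesh = mesh, times = times, snapshots = snaps,
                 scheme = scheme,
                 regime = if (!is.null(load)) load$regime else "none"),
            class = "field_solution")
}

# assemble K (elasticity), Q (coupling), H (permeability Laplacian),
# S (pressure-increment stabilisation)
.assemble_biot <- function(mesh, g, matE, stab_beta) {
  ne <- nrow(mesh$tri); n <- nrow(mesh$nodes)
  b <- g$b; cc <- g$c; A <- g$area
  G <- matE$G; lam <- matE$lambda; alp <- matE$alpha
  kin <- matE$k_int; Mc <- matE$M_conf
  # elasticity: D = [[lam+2G, lam, 0], [lam, lam+2G, 0], [0, 0, G]]
  iK <- jK <- integer(36L * ne); vK <- numeric(36L * ne)
  iQ <- jQ <- integer(18L * ne); vQ <- numeric(18L * ne)
  iH <- jH <- integer(9L * ne); vH <- numeric(9L * ne)
  vS <- numeric(9L * ne)
  h2 <- 2 * A                     # characteristic element length^2
  eps_stab <- stab_beta * h2 / Mc
  ptr_K <- 0L; ptr_Q <- 0L; ptr_H <- 0L
  for (a in 1:3) for (bb in 1:3) {
    Ba <- b[, a]; Ca <- cc[, a]; Bb <- b[, bb]; Cb <- cc[, bb]
    kxx <- A * ((lam + 2 * G) * Ba * Bb + G * Ca * Cb)
    kxz <- A * (lam * Ba * Cb + G * Ca * Bb)
    kzx <- A * (lam * Ca * Bb + G * Ba * Cb)
    kzz <- A * ((lam + 2 * G) * Ca * Cb + G * Ba * Bb)
    na <- mesh$tri[, a]; nb <- mesh$tri[, bb]
    idx <- ptr_K + seq_len(4L * ne)
    iK[idx] <- c(2 * na - 1L, 2 * na - 1L, 2 * na, 2 * na)
    jK[idx] <- c(2 * nb - 1L, 2 * nb, 2 * nb - 1L, 2 * nb)
    vK[idx] <- c(kxx, kxz, kzx, kzz)
    ptr_K <- ptr_K + 4L * ne
    # coupling: Q[u-dof, p-node] = alpha * grad_coeff * A/3
    idxq <- ptr_Q + seq_len(2L * ne)
    iQ[idxq] <- c(2 * na - 1L, 2 * na)
    jQ[idxq] <- c(nb, nb)
    vQ[idxq] <- c(alp * Ba * A / 3, alp * Ca * A / 3)
    ptr_Q <- ptr_Q + 2L * ne
    # permeability + stabilisation Laplacians
    idxh <- ptr_H + seq_len(ne)
    iH[idxh] <- na; jH[idxh] <- nb
    lap <- A * (Ba * Bb + Ca * Cb)
    vH[idxh] <- kin * lap
    vS[idxh] <- eps_stab * lap
    ptr_H <- ptr_H + ne
  }
  dims_u <- c(2L * n, 2L * n)
  list(
    K = Matrix::sparseMatrix(i = iK, j = jK, x = vK, dims = dims_u),
    Q = Matrix::sparseMatrix(i = iQ, j = jQ, x = vQ, dims = c(2L * n, n)),
    H = Matrix::sparseMatrix(i = iH, j = jH, x = vH, dims = c(n, n)),
    S = Matrix::sparseMatrix(i = iH, j = jH, x = vS, dims = c(n, n))
  )
}

# nodal force vector (internal mN units) from a load case, plus optional
# edge tractions list(nodes, traction = c(tx, tz) in kPa, length in mm)
.load_vector <- function(mesh, load, n) {
  f <- numeric(2L * n)
  if (is.null(load)) return(f)
  if (inherits(load, "load_case")) {
    for (m in load$muscles) {
      nodes <- .resolve_nodes(mesh, m$node_set)
      if (length(nodes) == 0) stop("load: empty attachment set ", m$node_set)
      per_node <- m$magnitude_uN * 1e-3 * load$scale / length(nodes)  # mN
      f[2 * nodes - 1L] <- f[2 * nodes - 1L] + per_node * m$direction[1]
      f[2 * nodes] <- f[2 * nodes] + per_node * m$direction[2]
    }
  } else if (is.list(load) && !is.null(load$traction)) {
    # uniform traction on a straight boundary edge chain
    nodes <- .resolve_nodes(mesh, load$nodes)
    xy <- mesh$nodes[nodes, , drop = FALSE]
    ord <- order(xy[, 1], xy[, 2])
    nodes <- nodes[ord]; xy <- xy[ord, , drop = FALSE]
    seg <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                         xy[-nrow(xy), , drop = FALSE])^2))
    w <- numeric(length(nodes))
    w[-length(w)] <- w[-length(w)] + seg / 2
    w[-1] <- w[-1] + seg / 2
    f[2 * nodes - 1L] <- f[2 * nodes - 1L] + w * load$traction[1]
    f[2 * nodes] <- f[2 * nodes] + w * load$traction[2]
  } else {
    stop("unsupported load specification")
  }
  f
}

.postprocess <- function(mesh, g, matE, x, t_s, fac_load, f_full, asm,
                         fixed_u, tol) {
  n <- nrow(mesh$nodes)
  u <- matrix(x[seq_len(2L * n)], ncol = 2, byrow = TRUE)
  p <- x[2L * n + seq_len(n)]
  # equilibrium residual on free displacement dofs
  res <- as.numeric(asm$K %*% x[seq_len(2L * n)]) -
    as.numeric(asm$Q %*% p) - fac_load * f_full
  free_u <- setdiff(seq_len(2L * n), fixed_u)
  fnorm <- sqrt(sum((fac_load * f_full)^2))
  rel <- if (fnorm > 0) sqrt(sum(res[free_u]^2)) / fnorm else
    sqrt(sum(res[free_u]^2))
  if (fnorm > 0 && rel > tol) {
    stop("solve_poroelastic: equilibrium residual ", signif(rel, 3),
         " exceeds tolerance ", tol)
  }
  tri <- mesh$tri
  ux <- cbind(u[tri[, 1], 1], u[tri[, 2], 1], u[tri[, 3], 1])
  uz <- cbind(u[tri[, 1], 2], u[tri[, 2], 2], u[tri[, 3], 2])
  exx <- rowSums(g$b * ux)
  ezz <- rowSums(g$c * uz)
  gxz <- rowSums(g$c * ux) + rowSums(g$b * uz)
  lam <- matE$lambda; G <- matE$G; nu <- matE$nu
  sxx <- (lam + 2 * G) * exx + lam * ezz
  szz <- lam * exx + (lam + 2 * G) * ezz
  sxz <- G * gxz
  syy <- nu * (sxx + szz)       # out-of-plane (plane strain), effective
  vm <- von_mises(sxx, szz, sxz, s33 = syy)
  pr <- principal_stresses(sxx, szz, sxz)
  q <- darcy_flux(p, mesh, matE$k_int)
  list(t = t_s, load_factor = fac_load, u = u, p = p,
       elem = data.frame(
         sxx = sxx, szz = szz, sxz = sxz, soop = syy,
         vm = vm, s1 = pr[, 1], s2 = pr[, 2],
         qx = q[, 1], qz = q[, 2], qmag = sqrt(q[, 1]^2 + q[, 2]^2),
         p = (p[tri[, 1]] + p[tri[, 2]] + p[tri[, 3]]) / 3,
         label = mesh$label, area = g$area,
         stringsAsFactors = FALSE),
       equilibrium_residual = rel)
}

#' @exportS3Method base::print
print.field_solution <- function(x, ...) {
  cat("field_solution:", x$regime, "regime,", length(x$snapshots),
      "snapshot(s) over", max(x$times), "s;",
      nrow(x$mesh$tri), "elements\n")
  invisible(x)
}
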