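#' Build a triangle mesh of the joint cross-section
#'
#' Converts the frontal section of a knee volume into a conforming 2D
#' triangle mesh for the poroelastic solver. The femoral and tibiotarsal
#' cross-sections are labelled `cartilage`; the space between them (where the
#' rudiments face each other across at most `interzone_max` mm) is filled
#' with `interzone` elements. The section is resampled on a structured grid
#' of spacing `target_edge` and each cell split into two right triangles, so
#' the minimum interior angle is 45 degrees by construction and element count
#' scales like 1/target_edge^2. Node indexing is 1-based.
#'
#' Node sets provided with the mesh: `fix_femur` (proximal femoral cut),
#' `fix_tibia` (distal tibiotarsal cut), and four muscle attachment patches —
#' `flexor_lat`, `flexor_med` on the lateral/medial proximal tibiotarsus and
#' `extensor_lat`, `extensor_med` on the lateral/medial femur just proximal
#' of the condyles (capsular condensation level). The `capsule` set holds the
#' external boundary nodes of the interzone: the joint-capsule margin, which
#' can be sealed against drainage in the solver constraints.
#'
#' @param volume a `shape_volume`.
#' @param plane frontal plane spec `list(axis = "y", index = row)`; defaults
#'   to the located midline plane.
#' @param target_edge element edge length, mm.
#' @param interzone_max maximum femur-tibiotarsus facing distance filled with
#'   interzone tissue, mm.
#' @param crop list(below, above): how far the mesh extends distal of the
#'   tibiotarsus top and proximal of the fossa floor, mm.
#' @param min_angle_deg minimum acceptable element interior angle.
#' @return A `joint_mesh`: list(nodes n x 2 mm, tri ne x 3, label,
#'   rudiment, node_sets, boundary = list(external, interface), h).
#' @export
phantom_to_mesh <- function(volume, plane = NULL, target_edge = 0.02,
                            interzone_max = 0.30,
                            crop = list(below = 0.35, above = 0.35),
                            min_angle_deg = 30) {
  seg <- segment_rudiments(volume)
  if (is.null(plane)) plane <- locate_section_planes(volume, .seg = seg)$midline
  stopifnot(identical(plane$axis, "y"))
  vox <- volume$voxel_size
  Fm <- seg$femur[, plane$index, ]
  Tb <- seg$tibiotarsus[, plane$index, ]
  if (!any(Fm) || !any(Tb)) {
    stop("phantom_to_mesh: section plane misses femur or tibiotarsus")
  }
  nxv <- nrow(Fm); nzv <- ncol(Fm)
  # interzone pixels: strictly between facing rudiment surfaces
  Iz <- matrix(FALSE, nxv, nzv)
  fmin <- suppressWarnings(apply(Fm, 1, function(v) if (any(v)) min(which(v)) else NA))
  tmax <- suppressWarnings(apply(Tb, 1, function(v) if (any(v)) max(which(v)) else NA))
  gap_max_vox <- interzone_max / vox
  for (i in seq_len(nxv)) {
    if (!is.na(fmin[i]) && !is.na(tmax[i]) &&
        fmin[i] - tmax[i] - 1 > 0 && fmin[i] - tmax[i] - 1 <= gap_max_vox) {
      Iz[i, (tmax[i] + 1):(fmin[i] - 1)] <- TRUE
    }
  }
  if (!any(Iz)) stop("phantom_to_mesh: no interzone between the rudiments")

  z_tt_top <- max(which(apply(Tb, 2, any)))
  z_sb <- max(fmin, na.rm = TRUE)     # fossa floor datum on this slice
  z_lo_mm <- max(0, (z_tt_top - 0.5) * vox - crop$below)
  z_hi_mm <- min(nzv * vox, (z_sb - 0.5) * vox + crop$above)
  xs_occ <- which(apply(Fm | Tb, 1, any))
  x_lo_mm <- (min(xs_occ) - 1) * vox
  x_hi_mm <- max(xs_occ) * vox

  h <- target_edge
  ncx <- max(2L, as.integer(ceiling((x_hi_mm - x_lo_mm) / h)))
  ncz <- max(2L, as.integer(ceiling((z_hi_mm - z_lo_mm) / h)))
  cx <- x_lo_mm + (seq_len(ncx) - 0.5) * h
  cz <- z_lo_mm + (seq_len(ncz) - 0.5) * h
  ix <- pmin(pmax(ceiling(cx / vox), 1L), nxv)
  iz <- pmin(pmax(ceiling(cz / vox), 1L), nzv)
  lab <- matrix(NA_character_, ncx, ncz)
  for (a in seq_len(ncx)) {
    lab[a, ] <- ifelse(Fm[ix[a], iz], "femur",
                ifelse(Tb[ix[a], iz], "tibia",
                ifelse(Iz[ix[a], iz], "interzone", NA)))
  }
  mesh <- .cells_to_mesh(lab, x_lo_mm, z_lo_mm, h)
  if (length(mesh$tri) == 0) stop("phantom_to_mesh: meshing produced no elements")

  # node sets ----------------------------------------------------------------
  nodes <- mesh$nodes
  femur_nodes <- sort(unique(as.vector(mesh$tri[mesh$rudiment == "femur", ])))
  tibia_nodes <- sort(unique(as.vector(mesh$tri[mesh$rudiment == "tibia", ])))
  tol <- h / 4
  z_top <- max(nodes[femur_nodes, 2])
  z_bot <- min(nodes[tibia_nodes, 2])
  fix_femur <- femur_nodes[nodes[femur_nodes, 2] > z_top - tol]
  fix_tibia <- tibia_nodes[nodes[tibia_nodes, 2] < z_bot + tol]
  ext <- mesh$boundary$external
  tib_ext <- intersect(ext, tibia_nodes)
  fem_ext <- intersect(ext, femur_nodes)
  tzr <- range(nodes[tibia_nodes, 2])
  txr <- range(nodes[tibia_nodes, 1])
  mid_tib <- tib_ext[nodes[tib_ext, 2] > tzr[1] + 0.25 * diff(tzr) &
                     nodes[tib_ext, 2] < tzr[1] + 0.60 * diff(tzr)]
  flexor_lat <- mid_tib[nodes[mid_tib, 1] > txr[2] - tol]
  flexor_med <- mid_tib[nodes[mid_tib, 1] < txr[1] + tol]
  fxr <- range(nodes[femur_nodes, 1])
  cap_band <- fem_ext[nodes[fem_ext, 2] > (z_sb - 0.5) * vox + 0.05 &
                      nodes[fem_ext, 2] < (z_sb - 0.5) * vox + 0.30]
  extensor_lat <- cap_band[nodes[cap_band, 1] > fxr[2] - tol]
  extensor_med <- cap_band[nodes[cap_band, 1] < fxr[1] + tol]
  iz_nodes <- sort(unique(as.vector(
    mesh$tri[mesh$rudiment == "interzone", , drop = FALSE])))
  capsule <- intersect(ext, iz_nodes)
  sets <- list(fix_femur = fix_femur, fix_tibia = fix_tibia,
               flexor_lat = flexor_lat, flexor_med = flexor_med,
               extensor_lat = extensor_lat, extensor_med = extensor_med,
               capsule = capsule)
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0]
  if (length(empty)) {
    stop("phantom_to_mesh: empty node set(s): ", paste(empty, collapse = ", "))
  }
  out <- structure(list(
    nodes = nodes, tri = mesh$tri,
    label = ifelse(mesh$rudiment == "interzone", "interzone", "cartilage"),
    rudiment = mesh$rudiment,
    node_sets = sets, boundary = mesh$boundary, h = h,
    landmarks = list(fossa_floor_z = (z_sb - 0.5) * vox,
                     fossa_mid_x = {
                       lmk <- .slice_landmarks(Fm)
                       (mean(range(lmk$fossa_cols)) - 0.5) * vox
                     })
  ), class = "joint_mesh")
  q <- mesh_min_angle(out)
  if (q < min_angle_deg) {
    stop("phantom_to_mesh: mesh quality below threshold (min angle ",
         round(q, 1), " deg)")
  }
  out
}

# structured cells (labelled matrix, NA = empty) -> triangle mesh
.cells_to_mesh <- function(lab, x0, z0, h) {
  ncx <- nrow(lab); ncz <- ncol(lab)
  filled <- which(!is.na(lab), arr.ind = TRUE)
  if (nrow(filled) == 0) {
    return(list(nodes = matrix(0, 0, 2), tri = matrix(0L, 0, 3)))
  }
  # corner ids on the (ncx+1) x (ncz+1) point lattice
  nid <- function(i, j) (j - 1L) * (ncx + 1L) + i
  i <- filled[, 1]; j <- filled[, 2]
  n00 <- nid(i, j); n10 <- nid(i + 1L, j)
  n11 <- nid(i + 1L, j + 1L); n01 <- nid(i, j + 1L)
  tri_raw <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  rud <- rep(lab[filled], 2L)
  used <- sort(unique(as.vector(tri_raw)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri_raw], ncol = 3)
  gi <- ((used - 1L) %% (ncx + 1L)) + 1L
  gj <- ((used - 1L) %/% (ncx + 1L)) + 1L
  nodes <- cbind(x = x0 + (gi - 1L) * h, z = z0 + (gj - 1L) * h)
  # boundary edges: edges used by exactly one triangle
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ekey)
  bkey <- names(tab)[tab == 1L]
  bnodes <- sort(unique(as.integer(unlist(strsplit(bkey, " ")))))
  # interface nodes: shared by cartilage-ish and interzone elements
  is_iz <- rud == "interzone"
  iz_nodes <- unique(as.vector(tri[is_iz, , drop = FALSE]))
  ca_nodes <- unique(as.vector(tri[!is_iz, , drop = FALSE]))
  list(nodes = nodes, tri = tri, rudiment = rud,
       boundary = list(external = bnodes,
                       interface = sort(intersect(iz_nodes, ca_nodes))))
}

#' Structured rectangular strip mesh
#'
#' Builds an `nx` x `nz` cell rectangle of right triangles (verification
#' meshes: patch test, 1D consolidation column). Node sets `left`, `right`,
#' `bottom`, `top` hold the boundary nodes of each side.
#'
#' @param nx,nz cells along x and z.
#' @param Lx,Lz side lengths, mm.
#' @param label element tissue label.
#' @return a `joint_mesh`.
#' @export
rect_mesh <- function(nx, nz, Lx, Lz, label = "cartilage") {
  lab <- matrix(label, nx, nz)
  m <- .cells_to_mesh(lab, 0, 0, NA)
  # rebuild coordinates with anisotropic spacing
  nidx <- seq_len((nx + 1) * (nz + 1))
  gi <- ((nidx - 1L) %% (nx + 1L))
  gj <- ((nidx - 1L) %/% (nx + 1L))
  nodes <- cbind(x = gi * Lx / nx, z = gj * Lz / nz)
  tol_x <- Lx / nx / 4; tol_z <- Lz / nz / 4
  structure(list(
    nodes = nodes, tri = m$tri, label = m$rudiment, rudiment = m$rudiment,
    node_sets = list(
      left = which(nodes[, 1] < tol_x),
      right = which(nodes[, 1] > Lx - tol_x),
      bottom = which(nodes[, 2] < tol_z),
      top = which(nodes[, 2] > Lz - tol_z)
    ),
    boundary = m$boundary, h = max(Lx / nx, Lz / nz)
  ), class = "joint_mesh")
}

#' Element areas and shape-function gradients
#'
#' @param mesh a `joint_mesh`.
#' @return list(area ne, b ne x 3, c ne x 3): gradient of shape function of
#'   local node k is (b[, k], c[, k]).
#' @export
tri_geometry <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  if (any(det <= 0)) stop("tri_geometry: inverted or degenerate elements")
  area <- det / 2
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  cc <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  list(area = area, b = b, c = cc)
}

#' Element centroids
#' @param mesh a `joint_mesh`.
#' @return ne x 2 matrix.
#' @export
tri_centroids <- function(mesh) {
  (mesh$nodes[mesh$tri[, 1], , drop = FALSE] +
   mesh$nodes[mesh$tri[, 2], , drop = FALSE] +
   mesh$nodes[mesh$tri[, 3], , drop = FALSE]) / 3
}

#' Minimum interior angle of the mesh (degrees)
#' @param mesh a `joint_mesh`.
#' @return smallest interior angle over all elements.
#' @export
mesh_min_angle <- function(mesh) {
  ang <- function(a, b, cc) {
    v1 <- b - a; v2 <- cc - a
    acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
      sqrt(rowSums(v1^2) * rowSums(v2^2)))))
  }
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  min(ang(p1, p2, p3), ang(p2, p3, p1), ang(p3, p1, p2)) * 180 / pi
}

#' @exportS3Method base::print
print.joint_mesh <- function(x, ...) {
  cat("joint_mesh:", nrow(x$nodes), "nodes,", nrow(x$tri), "elements (",
      paste(names(table(x$label)), table(x$label), collapse = ", "),
      "), h =", x$h, "mm\n")
  invisible(x)
}

#' Write a mesh and fields as VTK legacy unstructured grid
#'
#' @param mesh a `joint_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node vectors/matrices.
#' @param cell_data named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0",
               "joint section", "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "float")), con)
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  writeLines(paste("CELLS", ne, 4 * ne), con)
  writeLines(paste(3, mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                   mesh$tri[, 3] - 1L), con)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(as.character(rep(5L, ne)), con)
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(c(paste("VECTORS", nm, "float")), con)
        writeLines(paste(v[, 1], v[, 2], 0), con)
      } else {
        writeLines(c(paste("SCALARS", nm, "float 1"),
                     "LOOKUP_TABLE default"), con)
        writeLines(as.character(v), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(paste("CELL_DATA", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(paste("SCALARS", nm, "float 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(as.character(cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
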