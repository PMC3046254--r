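#' Extract the cartilage outline on a virtual section
#'
#' Traces the boundary of the femoral cross-section at sub-voxel resolution:
#' the binary slice is anti-aliased with a small box filter and the 0.5
#' iso-contour is extracted by linear interpolation, then the largest closed
#' polygon is kept. Anatomical anchors are computed when the section shows the
#' two-condyle/fossa configuration: straight-line fits (principal axes) to the
#' medial and lateral sides and the intercondylar fossa midpoint.
#'
#' @param volume a `shape_volume`.
#' @param plane list(axis = "y", index = voxel row) frontal section; defaults
#'   to the located midline plane.
#' @param rudiment which rudiment to outline ("femur" default).
#' @param blur half-width (voxels) of the anti-aliasing box filter.
#' @return A `joint_outline`: list(polygon = n x 2 matrix (x, z in mm, open
#'   ring), anchors = list(medial_line, lateral_line, fossa_mid) or NULL,
#'   plane).
#' @export
extract_outline <- function(volume, plane = NULL, rudiment = "femur",
                            blur = 1L) {
  seg <- segment_rudiments(volume)
  if (is.null(plane)) {
    plane <- locate_section_planes(volume, .seg = seg)$midline
  }
  stopifnot(plane$axis == "y")
  mask <- seg[[if (rudiment == "femur") "femur" else "tibiotarsus"]]
  sl <- mask[, plane$index, ]
  if (!any(sl)) stop("extract_outline: no cartilage on the requested plane")
  vox <- volume$voxel_size
  f <- .box_blur(sl * 1, blur)
  xs <- (seq_len(nrow(f)) - 0.5) * vox
  zs <- (seq_len(ncol(f)) - 0.5) * vox
  cl <- grDevices::contourLines(xs, zs, f, levels = 0.5)
  if (length(cl) == 0) stop("extract_outline: contouring failed")
  areas <- vapply(cl, function(p) abs(.shoelace(cbind(p$x, p$y))), numeric(1))
  best <- cl[[which.max(areas)]]
  poly <- cbind(x = best$x, z = best$y)
  # drop duplicated closing vertex if present
  n <- nrow(poly)
  if (n > 1 && all(abs(poly[1, ] - poly[n, ]) < 1e-12)) {
    poly <- poly[-n, , drop = FALSE]
  }
  anchors <- tryCatch(.outline_anchors(sl, poly, vox), error = function(e) NULL)
  structure(list(polygon = poly, anchors = anchors, plane = plane),
            class = "joint_outline")
}

.box_blur <- function(m, r) {
  if (r <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- function(mat, k) {
    rbind(matrix(0, k, ncol(mat) + 2 * k),
          cbind(matrix(0, nrow(mat), k), mat, matrix(0, nrow(mat), k)),
          matrix(0, k, ncol(mat) + 2 * k))
  }
  p <- pad(m, r)
  out <- matrix(0, n1, n2)
  w <- (2 * r + 1)^2
  for (di in -r:r) for (dj in -r:r) {
    out <- out + p[(1 + r + di):(n1 + r + di), (1 + r + dj):(n2 + r + dj)]
  }
  out / w
}

.shoelace <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Perimeter of an outline polygon
#' @param outline a `joint_outline` or n x 2 matrix.
#' @return perimeter, mm.
#' @export
outline_perimeter <- function(outline) {
  poly <- if (inherits(outline, "joint_outline")) outline$polygon else outline
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(sqrt(rowSums((poly[j, , drop = FALSE] - poly) ^ 2)))
}

# anchors from the binary slice landmarks + PCA line fits on boundary points
.outline_anchors <- function(sl, poly, vox) {
  lm <- .slice_landmarks(sl)
  fossa_mid <- c(x = (mean(range(lm$fossa_cols)) - 0.5) * vox,
                 z = (lm$z_ff - 1) * vox)
  fit_side <- function(side) {
    xr <- range(poly[, 1])
    band <- 0.08 * diff(xr)
    pts <- if (side == "medial") {
      poly[poly[, 1] <= xr[1] + band, , drop = FALSE]
    } else {
      poly[poly[, 1] >= xr[2] - band, , drop = FALSE]
    }
    if (nrow(pts) < 3) stop("too few side points")
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    dir <- sv$v[, 1]
    if (dir[2] < 0) dir <- -dir  # orient distal->proximal
    list(point = ctr, dir = dir)
  }
  list(medial_line = fit_side("medial"), lateral_line = fit_side("lateral"),
       fossa_mid = fossa_mid)
}

#' Rigidly overlay cartilage outlines
#'
#' Aligns each outline by a rigid transform (rotation + translation, no
#' scaling): the mean side-line direction is rotated to the proximo-distal
#' axis and the fossa midpoint translated to the origin, mirroring the manual
#' overlay procedure (side lines parallel, fossa midpoints coincident).
#' Reports per-outline sector metrics in the common frame: fossa, medial and
#' lateral condyle widths on a scanline just distal of the fossa floor, and
#' total outline area.
#'
#' @param outlines list of >= 2 `joint_outline` objects with anchors.
#' @param scan_offset distance (mm) distal of the fossa floor at which sector
#'   widths are read.
#' @return List with `aligned` (list of `joint_outline` in the common frame)
#'   and `report` (data frame: outline, fossa_width, medial_width,
#'   lateral_width, area_mm2).
#' @export
overlay_outlines <- function(outlines, scan_offset = 0.03) {
  if (!is.list(outlines) || length(outlines) < 2) {
    stop("overlay_outlines: need at least two outlines")
  }
  aligned <- lapply(outlines, align_outline)
  rep_rows <- lapply(seq_along(aligned), function(k) {
    w <- .sector_widths(aligned[[k]]$polygon, scan_offset)
    data.frame(outline = k, fossa_width = w["fossa"],
               medial_width = w["medial"], lateral_width = w["lateral"],
               area_mm2 = abs(.shoelace(aligned[[k]]$polygon)),
               row.names = NULL)
  })
  list(aligned = aligned, report = do.call(rbind, rep_rows))
}

#' Align a single outline to the canonical overlay frame
#' @param outline a `joint_outline` with anchors.
#' @return the transformed `joint_outline`.
#' @export
align_outline <- function(outline) {
  if (is.null(outline$anchors)) {
    stop("align_outline: outline has no anatomical anchors")
  }
  a <- outline$anchors
  dir <- a$medial_line$dir + a$lateral_line$dir
  dir <- dir / sqrt(sum(dir^2))
  theta <- atan2(dir[1], dir[2])      # rotate dir onto +z axis
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ctr <- as.numeric(a$fossa_mid)
  tf <- function(pts) {
    sw <- sweep(as.matrix(pts), 2, ctr)
    sweep(sw %*% t(R), 2, c(0, 0), "+")
  }
  out <- outline
  out$polygon <- tf(outline$polygon)
  colnames(out$polygon) <- c("x", "z")
  out$anchors$fossa_mid <- c(x = 0, z = 0)
  out$anchors$medial_line <- list(point = as.numeric(tf(rbind(a$medial_line$point))),
                                  dir = as.numeric(rbind(a$medial_line$dir) %*% t(R)))
  out$anchors$lateral_line <- list(point = as.numeric(tf(rbind(a$lateral_line$point))),
                                   dir = as.numeric(rbind(a$lateral_line$dir) %*% t(R)))
  out
}

# widths along the scanline z = -offset (condyle region lies below the fossa
# floor after alignment): crossings sorted in x give medial condyle, fossa
# gap, lateral condyle extents
.sector_widths <- function(poly, offset) {
  z0 <- -abs(offset)
  n <- nrow(poly)
  j <- c(2:n, 1)
  z1 <- poly[, 2]; z2 <- poly[j, 2]
  cross <- which((z1 - z0) * (z2 - z0) < 0)
  if (length(cross) < 4) {
    return(c(fossa = NA_real_, medial = NA_real_, lateral = NA_real_))
  }
  t <- (z0 - z1[cross]) / (z2[cross] - z1[cross])
  xs <- sort(poly[cross, 1] + t * (poly[j, 1][cross] - poly[cross, 1]))
  m <- length(xs)
  # innermost gap around x = 0 is the fossa
  inner <- findInterval(0, xs)
  if (inner < 1 || inner >= m) {
    return(c(fossa = NA_real_, medial = NA_real_, lateral = NA_real_))
  }
  c(fossa = xs[inner + 1] - xs[inner],
    medial = xs[inner] - xs[1],
    lateral = xs[m] - xs[inner + 1])
}
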