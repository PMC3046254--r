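#' Segment the rudiments of a knee volume
#'
#' Splits the foreground of a binary knee volume into femur, tibiotarsus and
#' fibula using the joint architecture itself: the interzone gap separates the
#' femur (proximal, high z) from the lower-limb rudiments, and the fibula lies
#' lateral (+x) of the tibiotarsus across a medio-lateral gap. When the
#' rudiments touch (zero interzone), the split plane falls at the interior
#' z slice of minimum cross-sectional area.
#'
#' @param volume a `shape_volume`.
#' @return List with logical arrays `femur`, `tibiotarsus`, `fibula`, and
#'   `gap_voxels` (integer count of empty slices between femur and
#'   tibiotarsus along z, 0 if touching).
#' @export
segment_rudiments <- function(volume) {
  stopifnot(inherits(volume, "shape_volume"))
  vol <- volume$voxels
  occ <- apply(vol, 3, any)
  zocc <- which(occ)
  if (length(zocc) == 0) stop("segment_rudiments: empty volume")
  z_lo <- min(zocc); z_hi <- max(zocc)
  interior <- seq(z_lo, z_hi)
  empty_runs <- rle(!occ[interior])
  gap_voxels <- 0L
  if (any(empty_runs$values)) {
    # topmost interior run of empty slices = interzone gap
    ends <- cumsum(empty_runs$lengths)
    starts <- ends - empty_runs$lengths + 1L
    idx <- which(empty_runs$values)
    k <- idx[length(idx)]
    gap_voxels <- empty_runs$lengths[k]
    split_z <- interior[starts[k]] - 1L   # last occupied slice below the gap
  } else {
    # touching rudiments: split at minimum-area interior slice
    areas <- colSums(matrix(vol[, , interior], ncol = length(interior)))
    inner <- which(areas == min(areas[areas > 0]))
    split_z <- interior[inner[ceiling(length(inner) / 2)]] - 1L
  }
  femur <- vol
  femur[, , seq_len(min(split_z + gap_voxels, dim(vol)[3]))] <- FALSE
  lower <- vol & !femur
  # tibiotarsus vs fibula: medio-lateral gap in the lower region
  xocc <- apply(lower, 1, any)
  xr <- range(which(xocc))
  runs <- rle(xocc[xr[1]:xr[2]])
  comp <- which(runs$values)
  if (length(comp) < 2) {
    stop("segment_rudiments: fibula landmark not found (no medio-lateral gap ",
         "in the lower-limb region)")
  }
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  # medial-most occupied run = tibiotarsus, lateral-most = fibula
  tib_x <- (starts[comp[1]]:ends[comp[1]]) + xr[1] - 1L
  fib_x <- (starts[comp[length(comp)]]:ends[comp[length(comp)]]) + xr[1] - 1L
  tib <- array(FALSE, dim(vol)); fib <- array(FALSE, dim(vol))
  tib[tib_x, , ] <- lower[tib_x, , ]
  fib[fib_x, , ] <- lower[fib_x, , ]
  list(femur = femur, tibiotarsus = tib, fibula = fib,
       gap_voxels = gap_voxels)
}

# per-(x,y)-column lowest / highest occupied z slice (Inf / -Inf when empty)
.col_zmin <- function(vol) {
  d <- dim(vol)
  m <- matrix(Inf, d[1], d[2])
  for (z in rev(seq_len(d[3]))) m[vol[, , z]] <- z
  m
}
.col_zmax <- function(vol) {
  d <- dim(vol)
  m <- matrix(-Inf, d[1], d[2])
  for (z in seq_len(d[3])) m[vol[, , z]] <- z
  m
}

# condylar voxels of the femur: everything distal of the fossa-floor datum.
# The datum is the highest per-column minimum-z over the femur, which is the
# shaft's distal surface (fossa columns and any shaft overhang reach it).
.condylar_info <- function(femur) {
  zmin <- .col_zmin(femur)
  if (!any(is.finite(zmin))) stop("no femur voxels")
  z_sb <- max(zmin[is.finite(zmin)])
  count_y <- if (z_sb > 1) {
    apply(femur[, , seq_len(z_sb - 1L), drop = FALSE], 2, sum)
  } else {
    integer(ncol(zmin))
  }
  list(z_sb = z_sb, count_y = count_y)
}

#' Locate the virtual section planes
#'
#' Finds the consistent virtual sections used for the morphometric
#' measurements: a frontal (x-z) midline plane through the centroid row of
#' the condyle pair, a ventral-offset frontal plane, and the transverse plane
#' through the tibiotarsus/fibula proximal epiphyses. Deterministic given the
#' volume; index-based, hence exactly equivariant under voxel translations.
#'
#' @param volume a `shape_volume`.
#' @param ventral_frac offset of the ventral plane from the ventral-most
#'   condylar row, as a fraction of the condylar dorso-ventral extent.
#' @return A `section_set`: named list of planes, each `list(axis, index, mm)`.
#' @export
locate_section_planes <- function(volume, ventral_frac = 0.15,
                                  .seg = NULL) {
  seg <- if (is.null(.seg)) segment_rudiments(volume) else .seg
  info <- .condylar_info(seg$femur)
  if (sum(info$count_y) == 0) {
    stop("locate_section_planes: condyles not found distal of the fossa floor")
  }
  y_mid <- as.integer(round(stats::weighted.mean(seq_along(info$count_y),
                                                 info$count_y)))
  yr <- range(which(info$count_y > 0))
  y_ven <- as.integer(yr[1] + round(ventral_frac * (yr[2] - yr[1] + 1L)))
  # sanity: the midline slice must show two condyle runs around a fossa
  lm <- try(.slice_landmarks(seg$femur[, y_mid, ]), silent = TRUE)
  if (inherits(lm, "try-error")) {
    stop("locate_section_planes: intercondylar fossa landmark not detectable ",
         "on the candidate midline plane")
  }
  z_epi <- max(which(apply(seg$tibiotarsus, 3, any)))
  vox <- volume$voxel_size
  structure(list(
    midline = list(axis = "y", index = y_mid, mm = (y_mid - 0.5) * vox),
    ventral = list(axis = "y", index = y_ven, mm = (y_ven - 0.5) * vox),
    epiphyseal = list(axis = "z", index = z_epi, mm = (z_epi - 0.5) * vox)
  ), class = "section_set")
}

# landmarks of a frontal femur slice (x-z logical matrix):
# fossa floor z, condyle runs, fossa columns.
.slice_landmarks <- function(slice) {
  xocc <- which(apply(slice, 1, any))
  if (length(xocc) == 0) stop("empty femur slice")
  cmin <- vapply(xocc, function(i) min(which(slice[i, ])), integer(1))
  z_ff <- max(cmin)
  below <- cmin < z_ff
  runs <- rle(below)
  comp <- which(runs$values)
  if (length(comp) != 2) {
    stop("expected two condyle runs separated by the intercondylar fossa, ",
         "found ", length(comp))
  }
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  med <- xocc[starts[comp[1]]:ends[comp[1]]]
  lat <- xocc[starts[comp[2]]:ends[comp[2]]]
  fossa_cols <- (max(med) + 1L):(min(lat) - 1L)
  list(
    z_ff = z_ff,
    med_cols = med, lat_cols = lat, fossa_cols = fossa_cols,
    apex_med = min(cmin[match(med, xocc)]),
    apex_lat = min(cmin[match(lat, xocc)])
  )
}

#' Measure the twelve knee morphometric lengths
#'
#' Computes, on the located virtual sections, the twelve characteristic
#' lengths of the knee: tibiotarsus (i) and fibula (ii) proximal epiphyseal
#' widths, minimum interzone separation (iii), lateral (iv) and medial (v)
#' condyle heights from the fossa-floor datum to the condyle apex, the
#' dorso-ventral extent of the open intercondylar fossa (iv-b), and the
#' midline (vi, vii, iix) and ventral (ix, x, xi) widths of the lateral
#' condyle, fossa and medial condyle. All lengths in mm
#' (voxel count x voxel size).
#'
#' @param volume a `shape_volume`.
#' @param sections optional `section_set`; located automatically if missing.
#' @return A named numeric vector keyed i, ii, iii, iv, iv-b, v, vi, vii,
#'   iix, ix, x, xi, with attribute `sections`.
#' @export
measure_knee <- function(volume, sections = NULL) {
  seg <- segment_rudiments(volume)
  if (is.null(sections)) {
    sections <- locate_section_planes(volume, .seg = seg)
  }
  vox <- volume$voxel_size
  out <- stats::setNames(rep(NA_real_, 12),
                         c("i", "ii", "iii", "iv", "iv-b", "v",
                           "vi", "vii", "iix", "ix", "x", "xi"))

  width_at_top <- function(mask, z) {
    sl <- mask[, , z]
    xs <- which(apply(sl, 1, any))
    if (length(xs) == 0) stop("no rudiment voxels on the epiphyseal plane")
    (max(xs) - min(xs) + 1L) * vox
  }
  out["i"] <- width_at_top(seg$tibiotarsus, sections$epiphyseal$index)
  out["ii"] <- width_at_top(seg$fibula, sections$epiphyseal$index)

  # iii: minimum femur-tibiotarsus separation along z over shared columns
  out["iii"] <- {
    fmin <- .col_zmin(seg$femur)
    tmax <- .col_zmax(seg$tibiotarsus)
    shared <- is.finite(fmin) & is.finite(tmax)
    if (!any(shared)) stop("measure_knee [iii]: femur and tibiotarsus ",
                           "share no (x,y) columns")
    max(0, min(fmin[shared] - tmax[shared] - 1)) * vox
  }

  widths_on <- function(y_index) {
    lm <- .slice_landmarks(seg$femur[, y_index, ])
    c(lat = length(lm$lat_cols) * vox,
      fossa = length(lm$fossa_cols) * vox,
      med = length(lm$med_cols) * vox,
      z_ff = lm$z_ff, apex_lat = lm$apex_lat, apex_med = lm$apex_med,
      fossa_mid_col = lm$fossa_cols[ceiling(length(lm$fossa_cols) / 2)])
  }
  mid <- tryCatch(widths_on(sections$midline$index),
                  error = function(e) stop("measure_knee [vi,vii,iix]: ",
                                           conditionMessage(e)))
  ven <- tryCatch(widths_on(sections$ventral$index),
                  error = function(e) stop("measure_knee [ix,x,xi]: ",
                                           conditionMessage(e)))
  out["vi"] <- mid[["lat"]]; out["vii"] <- mid[["fossa"]]
  out["iix"] <- mid[["med"]]
  out["ix"] <- ven[["lat"]]; out["x"] <- ven[["fossa"]]
  out["xi"] <- ven[["med"]]
  out["iv"] <- (mid[["z_ff"]] - mid[["apex_lat"]]) * vox
  out["v"] <- (mid[["z_ff"]] - mid[["apex_med"]]) * vox

  # iv-b: dorso-ventral extent of the open fossa notch, probed one voxel
  # below the fossa-floor datum at the fossa mid column
  out["iv-b"] <- {
    info <- .condylar_info(seg$femur)
    x_f <- as.integer(mid[["fossa_mid_col"]])
    z_probe <- as.integer(mid[["z_ff"]]) - 1L
    cond_rows <- which(info$count_y > 0)
    open <- !seg$femur[x_f, cond_rows, z_probe]
    sum(open) * vox
  }

  attr(out, "sections") <- sections
  out
}

#' Measure a cohort of phantoms
#'
#' Convenience wrapper: generates `n` phantoms from jittered parameters and
#' measures each, returning a long-format data frame (one row per specimen x
#' measurement) suitable for the per-measurement ANOVA stage.
#'
#' @param n number of specimens.
#' @param treatment label stored with each specimen.
#' @param shape_simplification passed to [random_phantom_params()].
#' @param seed base seed; specimen k uses `seed + k`.
#' @param voxel_size voxel edge, mm.
#' @return Data frame with columns specimen, treatment, measurement,
#'   length_mm, ground_truth_mm.
#' @export
measure_cohort <- function(n, treatment, shape_simplification = 0, seed = 1,
                           voxel_size = 0.01) {
  rows <- lapply(seq_len(n), function(k) {
    pp <- random_phantom_params(seed + k, shape_simplification,
                                voxel_size = voxel_size)
    vol <- generate_joint_phantom(pp)
    m <- measure_knee(vol)
    data.frame(specimen = paste0(treatment, "_", k), treatment = treatment,
               measurement = names(m), length_mm = as.numeric(m),
               ground_truth_mm = as.numeric(vol$ground_truth[names(m)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
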