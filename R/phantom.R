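#' Parameters for the stylised embryonic knee phantom
#'
#' Builds and validates the parameter set describing a stylised voxel phantom
#' of the developing chick knee: a distal femur whose two condyles flank an
#' intercondylar fossa, a planar interzone gap, and proximal tibiotarsus and
#' fibula blocks. All lengths are in mm. Default values follow control-arm
#' day-4 morphometry of the modelled system (epiphyseal widths, condyle
#' heights and widths, fossa widths, interzone separation).
#'
#' `shape_simplification` in [0, 1] moves the phantom from a control-like
#' morphology (0) towards the immobilised phenotype (1): the intercondylar
#' fossa narrows, condyle heights shrink, the interzone thins and the
#' epiphyses narrow. The shrink factors at 1 mirror the strongest reported
#' immobilisation effects (fossa width ~43%, condyle heights ~16%,
#' interzone ~30%, epiphyseal widths ~19%).
#'
#' @param tt_width tibiotarsus proximal epiphyseal width (measurement i), mm.
#' @param fibula_width fibula proximal epiphyseal width (ii), mm.
#' @param interzone_gap minimum femur-tibiotarsus separation (iii), mm.
#' @param condyle_height_lat,condyle_height_med condyle heights (iv, v), mm,
#'   measured from the fossa-floor datum to the condyle apex along the
#'   distal-proximal axis.
#' @param fossa_height dorso-ventral extent of the open intercondylar fossa
#'   notch (iv-b), mm.
#' @param condyle_width_lat_mid,fossa_width_mid,condyle_width_med_mid midline
#'   section widths (vi, vii, iix), mm.
#' @param condyle_width_lat_ven,fossa_width_ven,condyle_width_med_ven ventral
#'   section widths (ix, x, xi), mm.
#' @param condylar_depth dorso-ventral (y) extent of the condylar region, mm.
#' @param ventral_slab_frac fraction of `condylar_depth` occupied by the
#'   ventral width slab.
#' @param shaft_length femoral shaft length above the fossa floor, mm.
#' @param tt_depth,tt_length tibiotarsus y-extent and z-extent, mm.
#' @param fibula_gap,fibula_depth medio-lateral gap between tibiotarsus and
#'   fibula, and fibula y-extent, mm.
#' @param shape_simplification scalar in [0, 1], see Details.
#' @param voxel_size edge length of a voxel, mm.
#' @param margin empty margin around the phantom, mm.
#' @param seed integer seed kept with the parameter set (sampling helpers use
#'   it; the generator itself is deterministic given the parameters).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(tt_width = 1.18,
                           fibula_width = 0.55,
                           interzone_gap = 0.08,
                           condyle_height_lat = 0.96,
                           condyle_height_med = 0.81,
                           fossa_height = 0.30,
                           condyle_width_lat_mid = 0.40,
                           fossa_width_mid = 0.29,
                           condyle_width_med_mid = 0.30,
                           condyle_width_lat_ven = 0.42,
                           fossa_width_ven = 0.31,
                           condyle_width_med_ven = 0.29,
                           condylar_depth = 0.40,
                           ventral_slab_frac = 0.35,
                           shaft_length = 0.60,
                           tt_depth = 0.60,
                           tt_length = 0.50,
                           fibula_gap = 0.12,
                           fibula_depth = 0.40,
                           shape_simplification = 0,
                           voxel_size = 0.01,
                           margin = 0.05,
                           seed = 1L) {
  p <- list(
    tt_width = tt_width, fibula_width = fibula_width,
    interzone_gap = interzone_gap,
    condyle_height_lat = condyle_height_lat,
    condyle_height_med = condyle_height_med,
    fossa_height = fossa_height,
    condyle_width_lat_mid = condyle_width_lat_mid,
    fossa_width_mid = fossa_width_mid,
    condyle_width_med_mid = condyle_width_med_mid,
    condyle_width_lat_ven = condyle_width_lat_ven,
    fossa_width_ven = fossa_width_ven,
    condyle_width_med_ven = condyle_width_med_ven,
    condylar_depth = condylar_depth,
    ventral_slab_frac = ventral_slab_frac,
    shaft_length = shaft_length,
    tt_depth = tt_depth, tt_length = tt_length,
    fibula_gap = fibula_gap, fibula_depth = fibula_depth,
    shape_simplification = shape_simplification,
    voxel_size = voxel_size, margin = margin, seed = as.integer(seed)
  )
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

# Shrink factors applied at shape_simplification = 1; chosen once to mirror
# the day-4 immobilisation effect sizes of the modelled system.
.simplification_factors <- c(
  fossa_width_mid = 0.43, fossa_width_ven = 0.43,
  condyle_height_lat = 0.16, condyle_height_med = 0.16,
  interzone_gap = 0.30,
  tt_width = 0.197, fibula_width = 0.184,
  condyle_width_lat_mid = 0.03, condyle_width_med_mid = 0.03,
  condyle_width_lat_ven = 0.06, condyle_width_med_ven = 0.06,
  fossa_height = 0.10
)

#' Effective (simplification-adjusted) phantom dimensions
#'
#' Applies the `shape_simplification` shrink factors to the raw parameter set
#' and returns the effective lengths actually built into the phantom. At
#' `shape_simplification = 0` this is the identity.
#'
#' @param params a `phantom_params` object.
#' @return A named list of effective lengths (mm) plus the untouched layout
#'   parameters.
#' @export
effective_phantom_dims <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  s <- params$shape_simplification
  eff <- unclass(params)
  for (nm in names(.simplification_factors)) {
    eff[[nm]] <- eff[[nm]] * (1 - .simplification_factors[[nm]] * s)
  }
  eff
}

validate_phantom_params <- function(p) {
  lens <- c(
    "tt_width", "fibula_width", "interzone_gap", "condyle_height_lat",
    "condyle_height_med", "fossa_height", "condyle_width_lat_mid",
    "fossa_width_mid", "condyle_width_med_mid", "condyle_width_lat_ven",
    "fossa_width_ven", "condyle_width_med_ven", "condylar_depth",
    "shaft_length", "tt_depth", "tt_length", "fibula_gap", "fibula_depth",
    "voxel_size", "margin"
  )
  for (nm in lens) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      if (nm %in% c("interzone_gap", "margin")) {
        if (is.numeric(p[[nm]]) && p[[nm]] >= 0) next  # gap/margin may be 0
      }
      stop("phantom_params: '", nm, "' must be a positive length (mm)")
    }
  }
  if (p$shape_simplification < 0 || p$shape_simplification > 1) {
    stop("phantom_params: shape_simplification must lie in [0, 1]")
  }
  if (p$ventral_slab_frac <= 0 || p$ventral_slab_frac >= 0.5) {
    stop("phantom_params: ventral_slab_frac must lie in (0, 0.5)")
  }
  eff <- local({
    s <- p$shape_simplification
    e <- unclass(p)
    for (nm in names(.simplification_factors)) {
      e[[nm]] <- e[[nm]] * (1 - .simplification_factors[[nm]] * s)
    }
    e
  })
  femur_w_mid <- eff$condyle_width_lat_mid + eff$fossa_width_mid +
    eff$condyle_width_med_mid
  if (eff$fossa_width_mid >= femur_w_mid) {
    stop("phantom_params: fossa wider than femur")  # unreachable but explicit
  }
  femur_w <- max(
    femur_w_mid,
    eff$condyle_width_lat_ven + eff$fossa_width_ven + eff$condyle_width_med_ven
  )
  if (femur_w > p$tt_width + p$fibula_gap + p$fibula_width + 2 * p$margin) {
    stop("phantom_params: femur wider than the tibiotarsus/fibula footprint; ",
         "rudiments would overlap the grid margin")
  }
  # The midline section must cut through the open part of the fossa notch:
  # the notch (fossa_height) must reach past the condylar centroid row.
  if (eff$fossa_height <= 0.55 * p$condylar_depth) {
    stop("phantom_params: fossa_height too small relative to condylar_depth; ",
         "midline section would miss the open fossa")
  }
  if (eff$fossa_height > p$condylar_depth) {
    stop("phantom_params: fossa_height exceeds condylar_depth")
  }
  invisible(p)
}

#' Sample a randomised phantom parameter set
#'
#' Draws a jittered parameter set around the defaults, for randomised
#' ground-truth-recovery sweeps and for simulating specimen-to-specimen
#' variation within a study arm. Multiplicative log-normal jitter with
#' coefficient of variation `cv` is applied to every measured length.
#'
#' @param seed integer seed.
#' @param shape_simplification passed through to [phantom_params()].
#' @param cv coefficient of variation of the jitter (default 0.04).
#' @param voxel_size voxel edge, mm.
#' @return A `phantom_params` object.
#' @export
random_phantom_params <- function(seed, shape_simplification = 0, cv = 0.04,
                                  voxel_size = 0.01) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  jitter1 <- function(x) x * exp(stats::rnorm(1L, 0, cv))
  phantom_params(
    tt_width = jitter1(1.18),
    fibula_width = jitter1(0.55),
    interzone_gap = jitter1(0.08),
    condyle_height_lat = jitter1(0.96),
    condyle_height_med = jitter1(0.81),
    fossa_height = jitter1(0.30),
    condyle_width_lat_mid = jitter1(0.40),
    fossa_width_mid = jitter1(0.29),
    condyle_width_med_mid = jitter1(0.30),
    condyle_width_lat_ven = jitter1(0.40),
    fossa_width_ven = jitter1(0.29),
    condyle_width_med_ven = jitter1(0.29),
    shape_simplification = shape_simplification,
    voxel_size = voxel_size,
    seed = as.integer(seed)
  )
}

#' Generate a voxel phantom of the developing knee
#'
#' Builds a binary voxel volume containing a distal femur (two box condyles on
#' a shaft, separated by a rectangular-profile intercondylar fossa open on the
#' ventral side), a planar interzone gap, and tibiotarsus + fibula blocks.
#' Axis convention: x = medial to lateral, y = ventral to dorsal,
#' z = distal to proximal. Every one of the twelve morphometric lengths is a
#' directly constructed dimension (snapped to whole voxels) and is returned in
#' `ground_truth` keyed i, ii, iii, iv, iv-b, v, vi, vii, iix, ix, x, xi.
#'
#' @param params a `phantom_params` object.
#' @return A `shape_volume` object: list with `voxels` (3D logical array),
#'   `voxel_size` (mm), `axes` (named convention), `ground_truth` (named mm).
#' @export
generate_joint_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  validate_phantom_params(params)
  eff <- effective_phantom_dims(params)
  vox <- params$voxel_size
  nv <- function(len) max(1L, as.integer(round(len / vox)))  # length in voxels

  # snapped construction lengths (voxels)
  v <- list(
    tt_w = nv(eff$tt_width), fib_w = nv(eff$fibula_width),
    gap = as.integer(round(eff$interzone_gap / vox)),  # may be 0
    h_lat = nv(eff$condyle_height_lat), h_med = nv(eff$condyle_height_med),
    d_f = nv(eff$fossa_height),
    w_lat_mid = nv(eff$condyle_width_lat_mid),
    wf_mid = nv(eff$fossa_width_mid),
    w_med_mid = nv(eff$condyle_width_med_mid),
    w_lat_ven = nv(eff$condyle_width_lat_ven),
    wf_ven = nv(eff$fossa_width_ven),
    w_med_ven = nv(eff$condyle_width_med_ven),
    T_y = nv(eff$condylar_depth),
    shaft = nv(eff$shaft_length),
    tt_d = nv(eff$tt_depth), tt_l = nv(eff$tt_length),
    fib_gap = nv(eff$fibula_gap), fib_d = nv(eff$fibula_depth),
    marg = max(2L, as.integer(round(eff$margin / vox)))
  )
  t_v <- max(1L, as.integer(round(params$ventral_slab_frac * v$T_y)))
  if (v$d_f <= t_v) stop("phantom_params: fossa notch shallower than ventral slab")

  femur_w_mid <- v$w_med_mid + v$wf_mid + v$w_lat_mid
  femur_w_ven <- v$w_med_ven + v$wf_ven + v$w_lat_ven

  nx <- v$marg + v$tt_w + v$fib_gap + v$fib_w + v$marg
  ny <- v$marg + max(v$T_y, v$tt_d, v$fib_d) + v$marg
  nz <- v$marg + v$tt_l + v$gap + max(v$h_lat, v$h_med) + v$shaft + v$marg
  vol <- array(FALSE, dim = c(nx, ny, nz))

  x_c <- v$marg + as.integer(round(v$tt_w / 2))         # fossa / tibia centre
  y0 <- v$marg                                          # ventral face row - 1
  z0 <- v$marg                                          # tibia base row - 1
  z_tt_top <- z0 + v$tt_l                               # last tibia slice
  z_apex <- z_tt_top + v$gap + 1L                       # lowest femur slice
  z_sb <- z_apex + max(v$h_lat, v$h_med)                # fossa floor datum
  # femur occupies z in [z_sb - h, z_sb - 1] for condyles, [z_sb, ...] shaft

  box <- function(xr, yr, zr) {
    vol[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <<- TRUE
  }

  # tibiotarsus + fibula
  box(c(x_c - as.integer(round(v$tt_w / 2)) + 1L,
        x_c - as.integer(round(v$tt_w / 2)) + v$tt_w),
      c(y0 + 1L, y0 + v$tt_d), c(z0 + 1L, z_tt_top))
  fib_x0 <- x_c - as.integer(round(v$tt_w / 2)) + v$tt_w + v$fib_gap
  box(c(fib_x0 + 1L, fib_x0 + v$fib_w),
      c(y0 + 1L, y0 + v$fib_d), c(z0 + 1L, z_tt_top))

  # condyle slabs: ventral rows [1, t_v], midline/dorsal rows [t_v+1, T_y]
  slab <- function(y_lo, y_hi, w_med, wf, w_lat) {
    half_f <- as.integer(round(wf / 2))
    # medial condyle
    box(c(x_c - half_f - w_med + 1L, x_c - half_f),
        c(y0 + y_lo, y0 + y_hi), c(z_sb - v$h_med, z_sb - 1L))
    # lateral condyle
    box(c(x_c + (wf - half_f) + 1L, x_c + (wf - half_f) + w_lat),
        c(y0 + y_lo, y0 + y_hi), c(z_sb - v$h_lat, z_sb - 1L))
  }
  slab(1L, t_v, v$w_med_ven, v$wf_ven, v$w_lat_ven)
  slab(t_v + 1L, v$T_y, v$w_med_mid, v$wf_mid, v$w_lat_mid)

  # dorsal fossa filler: condyles merge dorsal of the open notch
  if (v$d_f < v$T_y) {
    half_f <- as.integer(round(v$wf_mid / 2))
    fill_h <- max(1L, as.integer(round(min(v$h_lat, v$h_med) / 2)))
    box(c(x_c - half_f + 1L, x_c + (v$wf_mid - half_f)),
        c(y0 + v$d_f + 1L, y0 + v$T_y), c(z_sb - fill_h, z_sb - 1L))
  }

  # femoral shaft spanning the union condylar extent
  half_mid <- as.integer(round(v$wf_mid / 2))
  half_ven <- as.integer(round(v$wf_ven / 2))
  shaft_x0 <- min(x_c - half_mid - v$w_med_mid, x_c - half_ven - v$w_med_ven)
  shaft_x1 <- max(x_c + (v$wf_mid - half_mid) + v$w_lat_mid,
                  x_c + (v$wf_ven - half_ven) + v$w_lat_ven)
  box(c(shaft_x0 + 1L, shaft_x1), c(y0 + 1L, y0 + v$T_y),
      c(z_sb, z_sb + v$shaft - 1L))

  gt <- c(
    "i" = v$tt_w, "ii" = v$fib_w, "iii" = v$gap,
    "iv" = v$h_lat, "iv-b" = v$d_f, "v" = v$h_med,
    "vi" = v$w_lat_mid, "vii" = v$wf_mid, "iix" = v$w_med_mid,
    "ix" = v$w_lat_ven, "x" = v$wf_ven, "xi" = v$w_med_ven
  ) * vox

  structure(
    list(voxels = vol, voxel_size = vox,
         axes = c(x = "medial->lateral", y = "ventral->dorsal",
                  z = "distal->proximal"),
         ground_truth = gt,
         params = params),
    class = "shape_volume"
  )
}

#' @exportS3Method base::print
print.shape_volume <- function(x, ...) {
  cat("shape_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels @", x$voxel_size, "mm;",
      sum(x$voxels), "foreground voxels\n")
  if (!is.null(x$ground_truth)) {
    cat("ground truth (mm):\n")
    print(round(x$ground_truth, 4))
  }
  invisible(x)
}

#' Write / read a shape volume as NIfTI
#'
#' The binary volume is stored as an 8-bit NIfTI image with the voxel size in
#' the header; ground truth (if any) is written to a JSON sidecar next to it.
#'
#' @param volume a `shape_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_shape_volume` returns `path` invisibly; `read_shape_volume`
#'   returns a `shape_volume` (without construction parameters).
#' @export
write_shape_volume <- function(volume, path) {
  stopifnot(inherits(volume, "shape_volume"))
  img <- RNifti::asNifti(array(as.integer(volume$voxels), dim(volume$voxels)))
  RNifti::pixdim(img) <- rep(volume$voxel_size, 3)
  RNifti::writeNifti(img, path)
  if (!is.null(volume$ground_truth)) {
    jsonlite::write_json(as.list(volume$ground_truth),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_shape_volume
#' @export
read_shape_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  gt <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    gt <- unlist(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  structure(
    list(voxels = array(as.array(img) > 0.5, dim(img)), voxel_size = vox,
         axes = c(x = "medial->lateral", y = "ventral->dorsal",
                  z = "distal->proximal"),
         ground_truth = gt, params = NULL),
    class = "shape_volume"
  )
}
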