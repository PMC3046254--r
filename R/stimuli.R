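#' Default probe regions on a joint section mesh
#'
#' Builds the named anatomical probe regions used to quantify the stimulus
#' fields: cartilage boxes on the distal femur (adjacent to the intercondylar
#' fossa, and the dorsal/ventral portions of the medial and lateral condyles,
#' where "dorsal" maps to the proximal half and "ventral" to the distal half
#' of the condylar band in section coordinates), a patella region at the
#' lateral margin of the interzone, and the interzone sub-layers: the
#' chondrogenous layers (interzone elements within `band` mm of a cartilage
#' interface) and the intermediate layer (remaining mid-band).
#'
#' @param mesh a `joint_mesh` from [phantom_to_mesh()] (needs landmarks).
#' @param band chondrogenous-layer thickness from each interface, mm.
#' @param fossa_halfwidth half-width of the fossa-adjacent box, mm.
#' @return named list of `probe_region` objects.
#' @export
default_probe_regions <- function(mesh, band = 0.025, fossa_halfwidth = 0.18) {
  stopifnot(!is.null(mesh$landmarks))
  ctr <- tri_centroids(mesh)
  xf <- mesh$landmarks$fossa_mid_x
  zf <- mesh$landmarks$fossa_floor_z
  fem <- mesh$rudiment == "femur"
  if (!any(fem)) stop("default_probe_regions: no femoral elements")
  z_apex <- min(ctr[fem, 2])
  z_split <- (z_apex + zf) / 2
  x_med <- range(ctr[fem, 1])[1]
  x_lat <- range(ctr[fem, 1])[2]
  rect <- function(x0, x1, z0, z1) {
    cbind(x = c(x0, x1, x1, x0), z = c(z0, z0, z1, z1))
  }
  iz <- mesh$rudiment == "interzone"
  x_iz_max <- max(ctr[iz, 1])
  regions <- list(
    fossa_adjacent = probe_region("fossa_adjacent",
      polygon = rect(xf - fossa_halfwidth, xf + fossa_halfwidth,
                     z_apex, zf + 0.15), tissue = "cartilage"),
    dorsal_medial = probe_region("dorsal_medial",
      polygon = rect(x_med, xf - fossa_halfwidth, z_split, zf),
      tissue = "cartilage"),
    ventral_medial = probe_region("ventral_medial",
      polygon = rect(x_med, xf - fossa_halfwidth, z_apex, z_split),
      tissue = "cartilage"),
    dorsal_lateral = probe_region("dorsal_lateral",
      polygon = rect(xf + fossa_halfwidth, x_lat, z_split, zf),
      tissue = "cartilage"),
    ventral_lateral = probe_region("ventral_lateral",
      polygon = rect(xf + fossa_halfwidth, x_lat, z_apex, z_split),
      tissue = "cartilage"),
    patella_region = probe_region("patella_region",
      polygon = rect(x_iz_max - 0.15, x_iz_max + mesh$h,
                     min(ctr[iz, 2]) - mesh$h, max(ctr[iz, 2]) + mesh$h),
      tissue = "interzone"),
    chondrogenous_layer = probe_region("chondrogenous_layer",
      band = list(mode = "near_interface", dist = band),
      tissue = "interzone"),
    intermediate_layer = probe_region("intermediate_layer",
      band = list(mode = "mid", dist = band), tissue = "interzone")
  )
  # every region must intersect the mesh
  for (r in regions) {
    if (length(.region_elements(mesh, r)) == 0) {
      stop("default_probe_regions: region '", r$id, "' intersects no elements")
    }
  }
  regions
}

#' Construct a probe region
#'
#' @param id region identifier.
#' @param polygon optional k x 2 polygon (x, z in mm); element membership is
#'   by centroid inclusion.
#' @param band optional list(mode = "near_interface" or "mid", dist = mm) for
#'   interface-distance bands.
#' @param tissue optional tissue label filter ("cartilage"/"interzone").
#' @return a `probe_region`.
#' @export
probe_region <- function(id, polygon = NULL, band = NULL, tissue = NULL) {
  if (is.null(polygon) && is.null(band)) {
    stop("probe_region: give a polygon or a band definition")
  }
  structure(list(id = id, polygon = polygon, band = band, tissue = tissue),
            class = "probe_region")
}

# vectorised ray-casting point-in-polygon (boundary points count as inside)
.in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; zi <- poly[i, 2]
    xj <- poly[j, 1]; zj <- poly[j, 2]
    cross <- ((zi > pts[, 2]) != (zj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - zi) / (zj - zi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

.region_elements <- function(mesh, region) {
  ctr <- tri_centroids(mesh)
  keep <- rep(TRUE, nrow(ctr))
  if (!is.null(region$tissue)) keep <- keep & (mesh$label == region$tissue)
  if (!is.null(region$polygon)) {
    keep <- keep & .in_polygon(ctr, region$polygon)
  }
  if (!is.null(region$band)) {
    iface <- mesh$boundary$interface
    if (length(iface) == 0) stop("mesh has no interface nodes for band region")
    ip <- mesh$nodes[iface, , drop = FALSE]
    d <- vapply(seq_len(nrow(ctr)), function(i) {
      min(sqrt((ip[, 1] - ctr[i, 1])^2 + (ip[, 2] - ctr[i, 2])^2))
    }, numeric(1))
    keep <- keep & if (region$band$mode == "near_interface") {
      d <= region$band$dist
    } else {
      d > region$band$dist
    }
  }
  which(keep)
}

#' Area-weighted field statistics over a probe region
#'
#' @param sol a `field_solution` (first snapshot used unless `snapshot`
#'   given).
#' @param region a `probe_region`.
#' @param fields element-field columns to summarise.
#' @param snapshot snapshot index.
#' @return data.frame(region, field, mean, max): area-weighted mean and
#'   maximum over the intersected elements.
#' @export
sample_region <- function(sol, region,
                          fields = c("vm", "s1", "s2", "p", "qmag"),
                          snapshot = length(sol$snapshots)) {
  stopifnot(inherits(sol, "field_solution"), inherits(region, "probe_region"))
  idx <- .region_elements(sol$mesh, region)
  if (length(idx) == 0) {
    stop("sample_region: region '", region$id, "' intersects no elements")
  }
  el <- sol$snapshots[[snapshot]]$elem
  w <- el$area[idx]
  do.call(rbind, lapply(fields, function(f) {
    v <- el[[f]][idx]
    data.frame(region = region$id, field = f,
               mean = sum(w * v) / sum(w), max = max(v),
               stringsAsFactors = FALSE)
  }))
}

#' Per-element dynamic stimulation amplitude
#'
#' The amplitude of dynamic stimulation over a contraction cycle: per element
#' and field, |value at mid-flexion - value at mid-extension|. For a regime
#' with a single constant solution (rigid paralysis) the amplitude is
#' identically zero by definition.
#'
#' @param flex `field_solution` at the flexion snapshot.
#' @param ext `field_solution` at the extension snapshot, or NULL for a
#'   constant regime.
#' @param fields element fields to difference.
#' @return data.frame of per-element amplitudes (one column per field).
#' @export
dynamic_amplitude <- function(flex, ext = NULL,
                              fields = c("vm", "s1", "s2", "p", "qmag")) {
  stopifnot(inherits(flex, "field_solution"))
  a <- flex$snapshots[[length(flex$snapshots)]]$elem
  if (is.null(ext)) {
    out <- as.data.frame(lapply(fields, function(f) rep(0, nrow(a))))
    names(out) <- fields
    return(out)
  }
  stopifnot(inherits(ext, "field_solution"))
  if (!isTRUE(all.equal(flex$mesh$nodes, ext$mesh$nodes)) ||
      !identical(flex$mesh$tri, ext$mesh$tri)) {
    stop("dynamic_amplitude: meshes differ between the two solutions")
  }
  b <- ext$snapshots[[length(ext$snapshots)]]$elem
  out <- as.data.frame(lapply(fields, function(f) abs(a[[f]] - b[[f]])))
  names(out) <- fields
  out
}

#' Summarise stimulus fields per region for one regime
#'
#' @param solutions named list of `field_solution`s: `flex` and `ext` for the
#'   normal regime, or a single entry (e.g. `steady`) for paralysis.
#' @param regions named list of `probe_region`s.
#' @param regime label stored in the summary.
#' @param tension_threshold max principal stress below which a femoral
#'   element counts as non-tensile (kPa).
#' @return a `stimulus_summary`: list(regime, table (phase x region x field
#'   mean/max), background (phase x field interzone-wide area-weighted
#'   means), amplitude (region means of the dynamic amplitude),
#'   compressive_fraction per phase, tension_threshold).
#' @export
summarise_stimuli <- function(solutions, regions, regime,
                              tension_threshold = 0.005) {
  stopifnot(length(solutions) >= 1, !is.null(names(solutions)))
  fields <- c("vm", "s1", "s2", "p", "qmag")
  tab <- do.call(rbind, lapply(names(solutions), function(ph) {
    rows <- do.call(rbind, lapply(regions, function(r) {
      sample_region(solutions[[ph]], r, fields)
    }))
    rows$phase <- ph
    rows
  }))
  mesh <- solutions[[1]]$mesh
  # dynamic amplitude per region (0 for single-phase regimes)
  amp_el <- if (length(solutions) >= 2) {
    dynamic_amplitude(solutions[[1]], solutions[[2]], fields)
  } else {
    dynamic_amplitude(solutions[[1]], NULL, fields)
  }
  area <- solutions[[1]]$snapshots[[length(solutions[[1]]$snapshots)]]$elem$area
  amp <- do.call(rbind, lapply(regions, function(r) {
    idx <- .region_elements(mesh, r)
    do.call(rbind, lapply(fields, function(f) {
      data.frame(region = r$id, field = f,
                 amplitude = sum(area[idx] * amp_el[[f]][idx]) /
                   sum(area[idx]),
                 stringsAsFactors = FALSE)
    }))
  }))
  # compression dominance is judged on the distal femur (condylar region
  # distal of the fossa floor), the field of view of the section comparisons
  fem <- mesh$rudiment == "femur"
  if (!is.null(mesh$landmarks)) {
    fem <- fem & tri_centroids(mesh)[, 2] < mesh$landmarks$fossa_floor_z
  }
  cf <- vapply(solutions, function(sol) {
    el <- sol$snapshots[[length(sol$snapshots)]]$elem
    sum(el$area[fem & el$s2 < 0 & el$s1 <= tension_threshold]) /
      sum(el$area[fem])
  }, numeric(1))
  # interzone background: area-weighted field means over all interzone
  # elements, the reference for the sub-layer ordinal comparisons
  izel <- mesh$label == "interzone"
  bg <- do.call(rbind, lapply(names(solutions), function(ph) {
    el <- solutions[[ph]]$snapshots[[length(solutions[[ph]]$snapshots)]]$elem
    w <- el$area[izel]
    data.frame(phase = ph, field = fields,
               mean = vapply(fields, function(f) {
                 sum(w * el[[f]][izel]) / sum(w)
               }, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(regime = regime, table = tab, background = bg,
                 amplitude = amp,
                 compressive_fraction = cf,
                 tension_threshold = tension_threshold,
                 regions = names(regions)),
            class = "stimulus_summary")
}

#' Compare normal and paralysis stimulus summaries
#'
#' Quantifies the regime contrast: per region x field the ratio of the
#' paralysis region mean to the normal peak (maximum over flexion/extension
#' phases) region mean; whether the Von Mises peak adjacent to the
#' intercondylar fossa persists in each regime (fossa region mean exceeding
#' the mean of the four condyle regions); whether peak tension is reduced
#' under paralysis relative to mid-flexion; and whether the paralysed femur
#' is predominantly compressive (area fraction with compressive minimum
#' principal stress and near-zero maximum principal stress at or above
#' `compression_fraction_min`); and the interzone sub-layer ordinals in the
#' normal regime (chondrogenous-layer fluid-velocity mean and
#' intermediate-layer pore-pressure mean above the interzone background
#' mean). Region means are compared at the regime peak (maximum over the
#' flexion/extension phases), background means likewise.
#'
#' @param normal `stimulus_summary` with phases flex/ext.
#' @param paralysis single-phase `stimulus_summary`.
#' @param compression_fraction_min area-fraction threshold for the
#'   "largely compression" flag.
#' @return a `comparison_report`: list(ratios data frame, flags list,
#'   thresholds).
#' @export
compare_regimes <- function(normal, paralysis,
                            compression_fraction_min = 0.7) {
  stopifnot(inherits(normal, "stimulus_summary"),
            inherits(paralysis, "stimulus_summary"))
  if (!setequal(normal$regions, paralysis$regions)) {
    stop("compare_regimes: region sets differ")
  }
  peak <- function(s) {
    stats::aggregate(mean ~ region + field, data = s$table, FUN = max)
  }
  a <- peak(normal); b <- peak(paralysis)
  m <- merge(a, b, by = c("region", "field"),
             suffixes = c("_normal", "_paralysis"))
  m$ratio <- m$mean_paralysis / m$mean_normal
  condyles <- c("dorsal_medial", "ventral_medial",
                "dorsal_lateral", "ventral_lateral")
  fossa_flag <- function(s) {
    pk <- peak(s)
    vm <- pk[pk$field == "vm", ]
    vm$mean[vm$region == "fossa_adjacent"] >
      mean(vm$mean[vm$region %in% condyles])
  }
  femoral <- c("fossa_adjacent", condyles)
  flex_tab <- normal$table[normal$table$phase == "flex", ]
  par_tab <- paralysis$table
  max_s1 <- function(tab) {
    s1 <- tab[tab$field == "s1" & tab$region %in% femoral, ]
    max(s1$mean)
  }
  pk_norm <- peak(normal)
  bg_norm <- stats::aggregate(mean ~ field, data = normal$background,
                              FUN = max)
  layer_peak <- function(region, field) {
    pk_norm$mean[pk_norm$region == region & pk_norm$field == field]
  }
  bg_peak <- function(field) bg_norm$mean[bg_norm$field == field]
  flags <- list(
    fossa_vm_peak_normal = fossa_flag(normal),
    fossa_vm_peak_paralysis = fossa_flag(paralysis),
    tension_reduced = max_s1(par_tab) < max_s1(flex_tab),
    paralysis_compression_dominant =
      max(paralysis$compressive_fraction) >= compression_fraction_min,
    paralysis_dynamic_amplitude_zero =
      all(paralysis$amplitude$amplitude == 0),
    chondrogenous_fluid_velocity_elevated =
      layer_peak("chondrogenous_layer", "qmag") > bg_peak("qmag"),
    intermediate_pressure_elevated =
      layer_peak("intermediate_layer", "p") > bg_peak("p")
  )
  structure(list(ratios = m, flags = flags,
                 compression_fraction = unname(paralysis$compressive_fraction[1]),
                 thresholds = list(
                   tension_threshold = paralysis$tension_threshold,
                   compression_fraction_min = compression_fraction_min)),
            class = "comparison_report")
}

#' @exportS3Method base::print
print.comparison_report <- function(x, ...) {
  cat("comparison_report: paralysis/normal mean-field ratios for",
      length(unique(x$ratios$region)), "regions\n")
  for (nm in names(x$flags)) cat("  ", nm, ":", x$flags[[nm]], "\n")
  invisible(x)
}
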