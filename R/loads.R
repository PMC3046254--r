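#' Default muscle table
#'
#' A documented fixture of four muscle point-load sets for the 2D joint
#' section: two flexors attached to the proximal tibiotarsus (the muscles
#' active during the flexion contraction) and two extensors attached at the
#' capsular condensation level of the femur (active during extension). Pull
#' directions are oblique: each muscle pulls towards the other rudiment, so
#' every regime loads the joint in compression. The flexors carry a strong
#' lateral component (dominant flexion bending/shear); the weaker extensors
#' pull medially, so simultaneous tetanic co-contraction spreads contact over
#' both condyles with the transverse components largely balancing out.
#' Magnitudes are configuration values, not measurements.
#'
#' @param flexor_uN,extensor_uN peak force per muscle, micro-newtons.
#' @return data.frame(name, node_set, dx, dz, magnitude_uN, group).
#' @export
default_muscle_table <- function(flexor_uN = 250, extensor_uN = 125) {
  tab <- data.frame(
    name = c("flexor_lateral", "flexor_medial",
             "extensor_lateral", "extensor_medial"),
    node_set = c("flexor_lat", "flexor_med", "extensor_lat", "extensor_med"),
    dx = c(0.45, 0.45, -0.30, -0.30),
    dz = c(0.95, 0.95, -0.95, -0.95),
    magnitude_uN = c(flexor_uN, flexor_uN, extensor_uN, extensor_uN),
    group = c("flexor_set", "flexor_set", "extensor_set", "extensor_set"),
    stringsAsFactors = FALSE
  )
  nrm <- sqrt(tab$dx^2 + tab$dz^2)
  tab$dx <- tab$dx / nrm; tab$dz <- tab$dz / nrm
  tab
}

#' Read / write a muscle table as CSV
#' @param path CSV path.
#' @param table data.frame as from [default_muscle_table()].
#' @return the table (read) or `path` invisibly (write).
#' @export
read_muscle_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "node_set", "dx", "dz", "magnitude_uN", "group")
  if (!all(need %in% names(tab))) {
    stop("muscle table must have columns ", paste(need, collapse = ", "))
  }
  tab
}

#' @rdname read_muscle_table
#' @export
write_muscle_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

.validate_muscles <- function(tab) {
  nrm <- sqrt(tab$dx^2 + tab$dz^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("muscle directions must be unit vectors")
  if (any(tab$magnitude_uN <= 0)) stop("muscle magnitudes must be positive")
  if (!all(tab$group %in% c("flexor_set", "extensor_set"))) {
    stop("muscle group must be flexor_set or extensor_set")
  }
  invisible(tab)
}

#' Build a muscle load case for a contraction regime
#'
#' Three regimes are supported. `flexion` and `extension` activate only their
#' muscle group at full magnitude with a ramped contraction cycle.
#' `paralysis` models rigid immobilisation (sustained tetanic contraction):
#' every muscle is applied simultaneously and continuously, scaled to
#' `paralysis_scale` of its normal peak (default 0.75, reflecting the reduced
#' force-generating capacity of immobilised muscle), so the total applied
#' magnitude is exactly `paralysis_scale` times the summed normal peaks.
#'
#' @param muscles muscle table (see [default_muscle_table()]).
#' @param regime one of "flexion", "extension", "paralysis".
#' @param paralysis_scale force scale applied in the paralysis regime.
#' @return a `load_case`: list(regime, muscles (list of name, node_set,
#'   direction, magnitude_uN), temporal ("ramped_cycle" or "constant"),
#'   scale, total_uN).
#' @export
build_load_case <- function(muscles, regime = c("flexion", "extension",
                                                "paralysis"),
                            paralysis_scale = 0.75) {
  regime <- match.arg(regime)
  .validate_muscles(muscles)
  stopifnot(paralysis_scale > 0, paralysis_scale <= 1)
  sel <- switch(regime,
    flexion = muscles$group == "flexor_set",
    extension = muscles$group == "extensor_set",
    paralysis = rep(TRUE, nrow(muscles))
  )
  if (!any(sel)) stop("build_load_case: no muscles in the required group ",
                      "for regime '", regime, "'")
  scale <- if (regime == "paralysis") paralysis_scale else 1
  sub <- muscles[sel, , drop = FALSE]
  structure(list(
    regime = regime,
    muscles = lapply(seq_len(nrow(sub)), function(i) {
      list(name = sub$name[i], node_set = sub$node_set[i],
           direction = c(sub$dx[i], sub$dz[i]),
           magnitude_uN = sub$magnitude_uN[i])
    }),
    temporal = if (regime == "paralysis") "constant" else "ramped_cycle",
    scale = scale,
    total_uN = scale * sum(sub$magnitude_uN)
  ), class = "load_case")
}

#' @exportS3Method base::print
print.load_case <- function(x, ...) {
  cat("load_case:", x$regime, "(", x$temporal, "),",
      length(x$muscles), "muscles, scale", x$scale,
      ", total", x$total_uN, "uN\n")
  invisible(x)
}
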