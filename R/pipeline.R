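#' Default pipeline configuration
#'
#' One configuration object drives both experiment recipes and is shared
#' across load regimes (the same mesh, materials, boundary conditions and
#' time schemes are reused for flexion, extension and paralysis). All units:
#' lengths mm, stresses kPa, forces uN, times s, permeability mm^4 N^-1 s^-1.
#'
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(
      voxel_size = 0.01,
      control = list(shape_simplification = 0),
      immobilised = list(shape_simplification = 1),
      n_per_arm = c(control = 16L, immobilised = 17L),
      jitter_cv = 0.04
    ),
    mesh = list(target_edge = 0.02, interzone_max = 0.30),
    materials = material_map(),
    muscles = default_muscle_table(),
    paralysis_scale = 0.75,
    time = list(
      contraction = time_scheme(total = 1, n_steps = 10, ramp = 0.5,
                                snapshots = 0.25),
      paralysis = time_scheme(total = 2e4, n_steps = 15, snapshots = 2e4)
    ),
    regions = list(band = 0.025, fossa_halfwidth = 0.18),
    stats = list(tension_threshold = 0.005, compression_fraction_min = 0.7),
    counts = count_sim_params(seed = as.integer(seed) + 977L)
  )
}

#' Write a configuration to YAML (materials and schemes flattened)
#' @param config configuration list.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(rapply(config, unclass, how = "replace"), path)
  invisible(path)
}

#' Run the stimuli-comparison experiment
#'
#' Builds the control phantom and its joint-section mesh, solves the
#' poroelastic model for mid-flexion, mid-extension and rigid-paralysis
#' steady state on the same mesh/materials/constraints, summarises the five
#' stimulus fields over the anatomical probe regions, and writes the regime
#' comparison. Fully deterministic: no stage consumes random numbers.
#'
#' @param config configuration from [default_config()].
#' @param out_dir output directory (created); NULL skips file output.
#' @param write_vtk_fields also write VTK field files per regime.
#' @return list(mesh, solutions, summaries, report, outputs).
#' @export
run_stimuli_experiment <- function(config = default_config(), out_dir = NULL,
                                   write_vtk_fields = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  phantom <- stage("phantom", {
    pp <- do.call(phantom_params, c(config$phantom$control,
                                    list(voxel_size = config$phantom$voxel_size)))
    generate_joint_phantom(pp)
  })
  mesh <- stage("mesh", phantom_to_mesh(
    phantom, target_edge = config$mesh$target_edge,
    interzone_max = config$mesh$interzone_max))
  # external surfaces drain freely except the joint-capsule margin of the
  # interzone, which is sealed: interzone fluid exits through the cartilage
  constraints <- list(fix = c("fix_femur", "fix_tibia"), drained = "external",
                      sealed = "capsule")
  solve_regime <- function(regime) {
    lc <- build_load_case(config$muscles, regime,
                          paralysis_scale = config$paralysis_scale)
    scheme <- if (regime == "paralysis") config$time$paralysis
              else config$time$contraction
    solve_poroelastic(mesh, config$materials, lc, scheme, constraints)
  }
  sols <- stage("solve", list(
    flex = solve_regime("flexion"),
    ext = solve_regime("extension"),
    steady = solve_regime("paralysis")
  ))
  regions <- stage("regions", default_probe_regions(
    mesh, band = config$regions$band,
    fossa_halfwidth = config$regions$fossa_halfwidth))
  summaries <- stage("summarise", list(
    normal = summarise_stimuli(sols[c("flex", "ext")], regions, "normal",
                               config$stats$tension_threshold),
    paralysis = summarise_stimuli(sols["steady"], regions, "paralysis",
                                  config$stats$tension_threshold)
  ))
  report <- stage("compare", compare_regimes(
    summaries$normal, summaries$paralysis,
    config$stats$compression_fraction_min))
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    long <- rbind(
      cbind(regime = "normal", summaries$normal$table),
      cbind(regime = "paralysis", summaries$paralysis$table)
    )
    names(long) <- sub("^mean$", "mean_kPa_or_mm_per_s", names(long))
    names(long) <- sub("^max$", "max_kPa_or_mm_per_s", names(long))
    f1 <- file.path(out_dir, "region_summary.csv")
    utils::write.csv(long, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "comparison_ratios.csv")
    utils::write.csv(report$ratios, f2, row.names = FALSE)
    f3 <- file.path(out_dir, "comparison_flags.json")
    jsonlite::write_json(
      c(report$flags,
        list(compression_fraction = report$compression_fraction,
             thresholds = report$thresholds)),
      f3, auto_unbox = TRUE, digits = NA)
    outputs <- c(f1, f2, f3)
    if (write_vtk_fields) {
      for (nm in names(sols)) {
        snap <- sols[[nm]]$snapshots[[length(sols[[nm]]$snapshots)]]
        fv <- file.path(out_dir, paste0("fields_", nm, ".vtk"))
        write_vtk(mesh, fv,
                  point_data = list(u = snap$u, p = snap$p),
                  cell_data = list(vm = snap$elem$vm, s1 = snap$elem$s1,
                                   s2 = snap$elem$s2, qmag = snap$elem$qmag))
        outputs <- c(outputs, fv)
      }
    }
  }
  list(mesh = mesh, solutions = sols, summaries = summaries, report = report,
       outputs = outputs)
}

#' Run the morphometry + proliferation experiment
#'
#' Generates a control and an immobilised arm of jittered phantoms, measures
#' the twelve lengths on each, runs the per-measurement one-way ANOVA with
#' percent reductions, then simulates the nested proliferation counts and
#' fits the binomial mixed model. Reproducible from config + seed. If the
#' ANOVA stage is infeasible (one specimen per arm) the measurements are
#' still returned/written and the comparison is skipped with a recorded
#' reason.
#'
#' @param config configuration from [default_config()].
#' @param out_dir output directory; NULL skips file output.
#' @return list(measurements, comparison (or NULL), skipped (reasons),
#'   counts, glmm, outputs).
#' @export
run_morphology_experiment <- function(config = default_config(),
                                      out_dir = NULL) {
  seed <- config$seed
  n <- config$phantom$n_per_arm
  meas <- rbind(
    measure_cohort(n[["control"]], "control",
                   config$phantom$control$shape_simplification,
                   seed = seed * 1000L,
                   voxel_size = config$phantom$voxel_size),
    measure_cohort(n[["immobilised"]], "immobilised",
                   config$phantom$immobilised$shape_simplification,
                   seed = seed * 1000L + 500L,
                   voxel_size = config$phantom$voxel_size)
  )
  skipped <- character(0)
  comparison <- NULL
  if (all(n >= 2)) {
    comparison <- compare_measurements(meas)
  } else {
    skipped <- c(skipped,
                 "group_comparison: fewer than 2 specimens per arm")
  }
  counts <- generate_proliferation_counts(config$counts)
  glmm <- tryCatch(fit_binomial_glmm(counts), error = function(e) {
    skipped <<- c(skipped, paste("glmm:", conditionMessage(e)))
    NULL
  })
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "measurements.csv")
    utils::write.csv(meas, f1, row.names = FALSE)
    outputs <- f1
    if (!is.null(comparison)) {
      cmp <- comparison
      names(cmp) <- sub("^mean_", "mean_mm_", names(cmp))
      f2 <- file.path(out_dir, "group_comparison.csv")
      utils::write.csv(cmp, f2, row.names = FALSE)
      outputs <- c(outputs, f2)
    }
    f3 <- file.path(out_dir, "proliferation_counts.csv")
    utils::write.csv(counts, f3, row.names = FALSE)
    outputs <- c(outputs, f3)
    if (!is.null(glmm)) {
      f4 <- file.path(out_dir, "glmm_result.json")
      jsonlite::write_json(
        list(effect_logodds = glmm$effect_logodds, se = glmm$se,
             effect_per_1000 = glmm$effect_per_1000,
             baseline = glmm$baseline, p_wald = glmm$p_wald,
             df_t = glmm$df_t, p_t = glmm$p_t,
             varcomp = as.list(glmm$varcomp),
             converged = glmm$converged, singular = glmm$singular),
        f4, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, f4)
    }
    if (length(skipped)) {
      writeLines(skipped, file.path(out_dir, "skipped_stages.txt"))
    }
  }
  list(measurements = meas, comparison = comparison, skipped = skipped,
       counts = counts, glmm = glmm, outputs = outputs)
}
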