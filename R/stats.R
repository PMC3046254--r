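#' Percent reduction of a treated mean relative to control
#'
#' @param control_mean,treated_mean group means (same units, control > 0).
#' @return 100 * (control - treated) / control.
#' @export
percent_reduction <- function(control_mean, treated_mean) {
  if (any(control_mean <= 0)) {
    stop("percent_reduction: control mean must be positive")
  }
  100 * (control_mean - treated_mean) / control_mean
}

#' Two-group one-way ANOVA
#'
#' The per-measurement group comparison: a one-way analysis of variance with
#' two groups, i.e. F on (1, n1 + n2 - 2) degrees of freedom, identical to
#' the squared pooled-variance two-sample t statistic. Backed by
#' `stats::lm`/`stats::anova`. Degenerate input (zero within-group variance
#' with equal means) returns F = 0, p = 1.
#'
#' @param control,treated numeric vectors (>= 2 values each).
#' @return list(F, df_num = 1, df_den, p, mean_control, mean_treated,
#'   percent_reduction).
#' @export
oneway_anova <- function(control, treated) {
  if (length(control) < 2 || length(treated) < 2) {
    stop("oneway_anova: need at least two values per group")
  }
  y <- c(control, treated)
  gr <- factor(rep(c("control", "treated"), c(length(control),
                                              length(treated))))
  df_den <- length(y) - 2L
  ssw <- sum((control - mean(control))^2) + sum((treated - mean(treated))^2)
  if (ssw == 0 && mean(control) == mean(treated)) {
    Fv <- 0; pv <- 1
  } else {
    # near-zero residual variance (voxel-identical specimens) triggers the
    # "essentially perfect fit" warning although F is well defined
    a <- suppressWarnings(stats::anova(stats::lm(y ~ gr)))
    Fv <- a[["F value"]][1]
    pv <- a[["Pr(>F)"]][1]
  }
  list(F = Fv, df_num = 1L, df_den = df_den, p = pv,
       mean_control = mean(control), mean_treated = mean(treated),
       percent_reduction = if (mean(control) > 0) {
         percent_reduction(mean(control), mean(treated))
       } else NA_real_)
}

#' Fit the nested binomial mixed-effects proliferation model
#'
#' Logistic-link binomial generalised linear mixed model with a fixed
#' treatment effect and random intercepts for individual and for section
#' nested within individual, estimated by the Laplace approximation
#' (`lme4::glmer`). Optionally adds region fixed effects and a
#' region-by-treatment interaction (for examining locations separately).
#' The fitted treatment effect is also converted to proliferating cells per
#' 1000 chondrocytes, evaluated at the control-arm fitted baseline. The
#' default inferential reference is the Wald z statistic; a t reference with
#' individual-level degrees of freedom (2 * n_individuals - 2), the
#' recommended test at small design sizes, is also reported.
#'
#' @param table a proliferation count table (see
#'   [generate_proliferation_counts()]).
#' @param by_region add region main effects (and interaction if
#'   `interaction`).
#' @param interaction add a region-by-treatment interaction.
#' @return a `glmm_result`: list(effect_logodds, se, z, p_wald, df_t, p_t,
#'   effect_per_1000, baseline, varcomp (individual, section), converged,
#'   singular, model).
#' @export
fit_binomial_glmm <- function(table, by_region = FALSE, interaction = FALSE) {
  need <- c("individual_id", "treatment", "section_id", "region",
            "n_total", "n_pos")
  if (!all(need %in% names(table))) {
    stop("fit_binomial_glmm: table must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(table$n_pos < 0 | table$n_pos > table$n_total)) {
    stop("fit_binomial_glmm: invalid counts (n_pos outside [0, n_total])")
  }
  n_ind <- tapply(table$individual_id, table$treatment,
                  function(x) length(unique(x)))
  if (any(n_ind < 2)) {
    stop("fit_binomial_glmm: need at least two individuals per arm ",
         "(individual-level variance inestimable)")
  }
  table$treatment <- stats::relevel(factor(table$treatment), ref = "control")
  table$region <- factor(table$region)
  rhs <- "treatment + (1 | individual_id) + (1 | individual_id:section_id)"
  if (by_region && interaction) rhs <- paste("region * ", rhs)
  else if (by_region) rhs <- paste("region + ", rhs)
  fml <- stats::as.formula(paste("cbind(n_pos, n_total - n_pos) ~", rhs))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = table, family = stats::binomial())
  ))
  co <- summary(fit)$coefficients
  row <- grep("^treatment", rownames(co))[1]
  est <- co[row, "Estimate"]; se <- co[row, "Std. Error"]
  z <- est / se
  df_t <- 2L * min(n_ind) - 2L
  baseline <- stats::plogis(co["(Intercept)", "Estimate"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_ind <- vc$sdcor[vc$grp == "individual_id"]
  v_sec <- vc$sdcor[vc$grp == "individual_id:section_id"]
  # boundary (singular) fits are flagged via `singular`, not `converged`
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv <- !any(grepl("failed to converge", msgs))
  structure(list(
    effect_logodds = est, se = se, z = z,
    p_wald = 2 * stats::pnorm(-abs(z)),
    df_t = df_t, p_t = 2 * stats::pt(-abs(z), df_t),
    effect_per_1000 = logodds_to_per1000(est, baseline),
    baseline = baseline,
    varcomp = c(individual = v_ind, section = v_sec),
    converged = conv, singular = lme4::isSingular(fit),
    model = fit
  ), class = "glmm_result")
}

#' @exportS3Method base::print
print.glmm_result <- function(x, ...) {
  cat("binomial GLMM treatment effect:",
      sprintf("%.4f log-odds (se %.4f), %.2f per 1000 at baseline %.4f\n",
              x$effect_logodds, x$se, x$effect_per_1000, x$baseline),
      sprintf("Wald z = %.3f, p = %.4f; t(df = %d) p = %.4f\n",
              x$z, x$p_wald, x$df_t, x$p_t))
  if (!x$converged) cat("  (convergence warning raised)\n")
  if (x$singular) cat("  (singular random-effects fit)\n")
  invisible(x)
}

#' Per-measurement group comparison table
#'
#' Runs [oneway_anova()] and [percent_reduction()] for every measurement in a
#' long-format morphometric table (as from [measure_cohort()]), producing one
#' row per measurement.
#'
#' @param measurements data frame with columns measurement, treatment,
#'   length_mm; the control arm must be labelled "control".
#' @return data frame: measurement, mean_control, mean_treated,
#'   percent_reduction, F, df_num, df_den, p.
#' @export
compare_measurements <- function(measurements) {
  stopifnot(all(c("measurement", "treatment", "length_mm") %in%
                names(measurements)))
  arms <- unique(measurements$treatment)
  if (length(arms) != 2 || !"control" %in% arms) {
    stop("compare_measurements: need a 'control' arm and one treated arm")
  }
  treated_arm <- setdiff(arms, "control")
  out <- lapply(unique(measurements$measurement), function(m) {
    sub <- measurements[measurements$measurement == m, ]
    a <- oneway_anova(sub$length_mm[sub$treatment == "control"],
                      sub$length_mm[sub$treatment == treated_arm])
    data.frame(measurement = m, mean_control = a$mean_control,
               mean_treated = a$mean_treated,
               percent_reduction = a$percent_reduction,
               F = a$F, df_num = a$df_num, df_den = a$df_den, p = a$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
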