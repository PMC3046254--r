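#' Simulation parameters for nested proliferation counts
#'
#' Describes the counting design: chondrocytes and mitotic (PH3-positive)
#' chondrocytes counted in a fixed-area box in each of five femoral regions
#' (1 = adjacent to the intercondylar fossa, 2/3 = dorsal/ventral medial
#' condyle, 4/5 = dorsal/ventral lateral condyle), on several sections nested
#' within individuals, with a configurable treatment effect. The default
#' design is 3 individuals per arm with counts from two independent focal
#' planes on each of two sections per specimen. The treatment effect may be
#' given on the log-odds scale or as a difference in proliferating cells per
#' 1000 (converted to log-odds at the region baseline); the default is a
#' reduction of 11.8 per 1000.
#'
#' @param n_individuals individuals per arm.
#' @param sections sections per individual.
#' @param planes focal planes per section (replicate counts).
#' @param baseline per-region baseline proliferation probability; recycled.
#' @param effect treatment effect size (immobilised minus control).
#' @param effect_scale "per_1000" or "log_odds".
#' @param sd_individual,sd_section random-intercept standard deviations on
#'   the log-odds scale (individual, and section within individual).
#' @param mean_n_total mean chondrocytes per counting box (Poisson).
#' @param seed integer seed.
#' @return a `count_sim_params`.
#' @export
count_sim_params <- function(n_individuals = 3, sections = 2, planes = 2,
                             baseline = c(0.045, 0.05, 0.05, 0.05, 0.05),
                             effect = -11.8, effect_scale = "per_1000",
                             sd_individual = 0.15, sd_section = 0.10,
                             mean_n_total = 500, seed = 1L) {
  baseline <- rep_len(baseline, 5L)
  stopifnot(all(baseline > 0), all(baseline < 1),
            sd_individual >= 0, sd_section >= 0,
            n_individuals >= 1, sections >= 1, planes >= 1,
            mean_n_total > 0,
            effect_scale %in% c("per_1000", "log_odds"))
  structure(list(n_individuals = n_individuals, sections = sections,
                 planes = planes, baseline = baseline, effect = effect,
                 effect_scale = effect_scale, sd_individual = sd_individual,
                 sd_section = sd_section, mean_n_total = mean_n_total,
                 seed = as.integer(seed)),
            class = "count_sim_params")
}

#' Convert a per-1000 proliferation difference to a log-odds effect
#'
#' @param per_1000 difference in proliferating cells per 1000 chondrocytes.
#' @param baseline control proliferation probability at which the conversion
#'   is evaluated.
#' @return log-odds difference.
#' @export
per1000_to_logodds <- function(per_1000, baseline) {
  p1 <- baseline + per_1000 / 1000
  stopifnot(p1 > 0, p1 < 1)
  stats::qlogis(p1) - stats::qlogis(baseline)
}

#' @rdname per1000_to_logodds
#' @param log_odds log-odds difference to convert back.
#' @export
logodds_to_per1000 <- function(log_odds, baseline) {
  (stats::plogis(stats::qlogis(baseline) + log_odds) - baseline) * 1000
}

#' Generate a nested proliferation count table
#'
#' Draws counts per box from a binomial whose log-odds are
#' baseline(region) + treatment effect + individual intercept + section
#' intercept, matching the nested design (sections within individuals,
#' replicate focal planes within sections). Reproducible given the seed.
#'
#' @param p a `count_sim_params`.
#' @return a `ProliferationTable` data frame: individual_id, treatment
#'   (control/immobilised), section_id, plane, region (1..5), n_total, n_pos.
#' @export
generate_proliferation_counts <- function(p) {
  stopifnot(inherits(p, "count_sim_params"))
  set.seed(p$seed)
  eff_lo <- if (p$effect_scale == "log_odds") {
    rep(p$effect, 5L)
  } else {
    vapply(p$baseline, function(b) per1000_to_logodds(p$effect, b), numeric(1))
  }
  rows <- list()
  for (arm in c("control", "immobilised")) {
    for (ind in seq_len(p$n_individuals)) {
      iid <- sprintf("%s_%02d", arm, ind)
      b_ind <- stats::rnorm(1, 0, p$sd_individual)
      for (sec in seq_len(p$sections)) {
        sid <- sprintf("%s_s%d", iid, sec)
        b_sec <- stats::rnorm(1, 0, p$sd_section)
        for (pl in seq_len(p$planes)) {
          n_tot <- stats::rpois(5L, p$mean_n_total)
          n_tot[n_tot == 0] <- 1L
          lo <- stats::qlogis(p$baseline) +
            (arm == "immobilised") * eff_lo + b_ind + b_sec
          n_pos <- stats::rbinom(5L, n_tot, stats::plogis(lo))
          rows[[length(rows) + 1L]] <- data.frame(
            individual_id = iid, treatment = arm, section_id = sid,
            plane = pl, region = 1:5, n_total = n_tot, n_pos = n_pos,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
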