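# Independent oracles used to cross-check package computations. These are
# deliberately written from the reference formulas, not by calling package
# internals.

# Terzaghi 1D consolidation series: p/p0 at normalised distance `zt` from the
# drained boundary (zt in [0, 1], drainage path H = 1) and time factor Tv.
oracle_terzaghi <- function(zt, Tv, n_terms = 200) {
  s <- 0
  for (m in 0:n_terms) {
    M <- (2 * m + 1) * pi / 2
    s <- s + 4 / (pi * (2 * m + 1)) * sin(M * zt) * exp(-M^2 * Tv)
  }
  s
}

# principal stresses of a 2D tensor via eigen decomposition (descending)
oracle_principal_eigen <- function(sxx, szz, sxz) {
  t(vapply(seq_along(sxx), function(i) {
    sort(eigen(matrix(c(sxx[i], sxz[i], sxz[i], szz[i]), 2, 2),
               symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }, numeric(2)))
}

# brute-force one-way ANOVA F from sums of squares
oracle_anova_F <- function(control, treated) {
  y <- c(control, treated)
  gm <- mean(y)
  ss_between <- length(control) * (mean(control) - gm)^2 +
    length(treated) * (mean(treated) - gm)^2
  ss_within <- sum((control - mean(control))^2) +
    sum((treated - mean(treated))^2)
  (ss_between / 1) / (ss_within / (length(y) - 2))
}

# squared pooled-variance two-sample t statistic
oracle_pooled_t2 <- function(control, treated) {
  n1 <- length(control); n2 <- length(treated)
  sp2 <- (sum((control - mean(control))^2) +
            sum((treated - mean(treated))^2)) / (n1 + n2 - 2)
  ((mean(control) - mean(treated)) / sqrt(sp2 * (1 / n1 + 1 / n2)))^2
}

# The default end-to-end stimuli experiment is used by several test files;
# run it once per session and cache the result.
.jm_cache <- new.env(parent = emptyenv())

cached_stimuli <- function() {
  if (is.null(.jm_cache$stimuli)) {
    .jm_cache$stimuli <- run_stimuli_experiment(default_config())
  }
  .jm_cache$stimuli
}

cached_phantom <- function() {
  if (is.null(.jm_cache$phantom)) {
    .jm_cache$phantom <- generate_joint_phantom(phantom_params())
  }
  .jm_cache$phantom
}

cached_mesh <- function() {
  if (is.null(.jm_cache$mesh)) {
    .jm_cache$mesh <- phantom_to_mesh(cached_phantom())
  }
  .jm_cache$mesh
}
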