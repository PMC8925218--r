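# Independent oracles and small fixture builders used across the suite.
# Each oracle is coded from first principles, separately from the package
# implementation it checks.

# Brute-force signed point-plane distance scan, one point at a time.
oracle_min_plane_distance <- function(cloud, point, normal) {
  best <- Inf
  for (i in seq_len(nrow(cloud))) {
    d <- sum((cloud[i, ] - point) * normal)
    if (d < best) best <- d
  }
  best
}

# Normal-equations solution of sigma ~ E*eps + eta*(eps*epsdot), no intercept.
oracle_normal_equations <- function(stress, strain, strain_rate) {
  x1 <- strain
  x2 <- strain * strain_rate
  A <- matrix(c(sum(x1 * x1), sum(x1 * x2),
                sum(x1 * x2), sum(x2 * x2)), 2, 2)
  b <- c(sum(x1 * stress), sum(x2 * stress))
  solve(A, b)
}

# Hand-coded finite differences: central interior, one-sided ends.
oracle_finite_diff <- function(y, t) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  for (i in 2:(n - 1)) d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

# Full 2^n enumeration of the signed-rank null; two-sided p for observed
# differences d (no zeros, no tied magnitudes assumed).
oracle_wilcoxon_enumeration <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Dense-quadrature loop and loading areas for an analytic cycle
# (eps(t), sigma(t)) sampled at n points: loop area via the shoelace on a
# very dense polygon, loading area via dense trapezoids.
oracle_loop_areas_dense <- function(eps_fun, sig_fun, t_end, n = 1e5) {
  t <- seq(0, t_end, length.out = n)
  x <- eps_fun(t); y <- sig_fun(t)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  loop <- 0.5 * abs(sum(x * yn - xn * y))
  imax <- which.max(x)
  xl <- x[1:imax]; yl <- y[1:imax]
  loading <- sum((yl[-1] + yl[-imax]) / 2 * diff(xl))
  list(loop = loop, loading = loading, edr = 100 * loop / loading)
}

# Random proper rotation matrix (det +1) via QR.
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Noiseless defaults used by round-trip tests.
noiseless_cohort_config <- function(...) cohort_config(noise_cv = 0, ...)
noiseless_gait_config <- function(...) gait_config(thickness_noise_sd = 0, ...)

# Simulate + analyze a single parameter set, returning heel_properties.
analyze_params <- function(p, gait = noiseless_gait_config(), seed = 1,
                           config = analysis_config()) {
  analyze_trial(simulate_stance(p, gait, seed = seed), config)
}

# Assemble a full analyzed cohort record table from a config.
analyzed_cohort <- function(cfg, gait, seed) {
  coh <- sample_cohort(cfg, seed)
  rows <- lapply(seq_len(nrow(coh)), function(i) {
    pr <- analyze_trial(simulate_stance(coh[i, ], gait))
    cbind(coh[i, c("subject_id", "side", "condition", "age", "bmi")],
          as.data.frame(pr))
  })
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  rec
}
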