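# Forward simulation of a stance-phase trial under the nonlinear
# Kelvin-Voigt model, and rendering of the corresponding 3D scene
# (marker balls + calcaneus point cloud) for the geometry stage.

#' Gait / acquisition configuration
#'
#' @param frame_rate acquisition frame rate (Hz); default 50.
#' @param gait_velocity nominal gait velocity (m/s); documentation only, the
#'   trajectory is parameterized by stance duration.
#' @param trajectory_shape `"asymmetric_cosine"` (cosine up / cosine down
#'   with `loading_fraction` of the stance spent loading) or
#'   `"raised_cosine"` (symmetric, loading fraction forced to 0.5).
#' @param loading_fraction fraction of stance duration spent loading.
#' @param ball_radius marker-ball radius (mm).
#' @param n_cloud_points points in the rendered calcaneus shell.
#' @param heel_area_cm2 heel contact area (cm^2), consumed as a scalar
#'   channel.
#' @param thickness_noise_sd additive thickness measurement noise SD (mm);
#'   0 disables.
#' @param plate_tilt_deg rigid tilt of plate, balls and cloud about the x
#'   axis (degrees).
#' @return A validated list of class `gait_config`.
#' @export
gait_config <- function(frame_rate = 50,
                        gait_velocity = 1.0,
                        trajectory_shape = c("asymmetric_cosine",
                                             "raised_cosine"),
                        loading_fraction = 0.45,
                        ball_radius = 5,
                        n_cloud_points = 500L,
                        heel_area_cm2 = 10,
                        thickness_noise_sd = 0.05,
                        plate_tilt_deg = 0) {
  trajectory_shape <- match.arg(trajectory_shape)
  assert_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  assert_number(loading_fraction, "loading_fraction", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(ball_radius, "ball_radius", lower = 0, strict_lower = TRUE)
  assert_number(n_cloud_points, "n_cloud_points", lower = 1)
  assert_number(heel_area_cm2, "heel_area_cm2", lower = 0, strict_lower = TRUE)
  assert_number(thickness_noise_sd, "thickness_noise_sd", lower = 0)
  assert_number(plate_tilt_deg, "plate_tilt_deg")
  structure(list(frame_rate = frame_rate, gait_velocity = gait_velocity,
                 trajectory_shape = trajectory_shape,
                 loading_fraction = if (trajectory_shape == "raised_cosine")
                   0.5 else loading_fraction,
                 ball_radius = ball_radius,
                 n_cloud_points = as.integer(n_cloud_points),
                 heel_area_cm2 = heel_area_cm2,
                 thickness_noise_sd = thickness_noise_sd,
                 plate_tilt_deg = plate_tilt_deg),
            class = "gait_config")
}

# Strain trajectory on a time grid: cosine rise over the loading phase,
# cosine fall over the unloading phase, 0 at both ends, peak at t_load.
strain_trajectory <- function(t, duration, peak, loading_fraction) {
  t_load <- loading_fraction * duration
  eps <- numeric(length(t))
  up <- t <= t_load
  eps[up] <- peak * (1 - cos(pi * t[up] / t_load)) / 2
  eps[!up] <- peak * (1 + cos(pi * (t[!up] - t_load) / (duration - t_load))) / 2
  eps
}

#' Simulate one stance-phase trial
#'
#' Samples the strain trajectory at `1/frame_rate`, evaluates the forward
#' nonlinear Kelvin-Voigt model `sigma = E*eps + eta*eps*eps_dot` on the
#' grid (with `eps_dot` the tangent of the sampled strain-time curve, i.e.
#' the same central-difference definition used at analysis time), and maps
#' the channels to observables: `thickness = h0*(1 - eps)`,
#' `force = sigma * area / 10`. Multiplicative Gaussian noise with
#' coefficient of variation `noise_cv` is applied to stress, and optional
#' additive Gaussian noise to thickness.
#'
#' @param params one cohort row ([sample_cohort()]) or a list with fields
#'   `h0_true`, `E_true`, `eta_true`, `peak_strain_true`, `stance_duration`,
#'   `noise_cv`.
#' @param gait a [gait_config()].
#' @param seed integer seed for the measurement noise; defaults to the
#'   cohort row's `trial_seed` when present.
#' @return A data frame of class `heel_trial` with columns `frame`, `time_s`,
#'   `thickness_mm`, `force_N`, `area_cm2` and attribute `truth` (noiseless
#'   strain, strain rate, stress and the generating parameters).
#' @export
#' @examples
#' coh <- sample_cohort(cohort_config(n_subjects = 1), seed = 1)
#' tr <- simulate_stance(coh[1, ], gait_config())
#' nrow(tr)
simulate_stance <- function(params, gait = gait_config(), seed = NULL) {
  p <- as.list(params)
  for (f in c("h0_true", "E_true", "eta_true", "peak_strain_true",
              "stance_duration", "noise_cv"))
    if (is.null(p[[f]]))
      stopf("'params' is missing field '%s'", f, class = "invalid_config_error")
  if (is.null(seed)) seed <- if (!is.null(p$trial_seed)) p$trial_seed else 1L
  n <- as.integer(round(p$stance_duration * gait$frame_rate)) + 1L
  if (n < 3L)
    stopf("stance_duration %.3g s spans fewer than 3 frames at %g Hz",
          p$stance_duration, gait$frame_rate,
          class = "degenerate_trajectory_error")
  t <- seq(0, by = 1 / gait$frame_rate, length.out = n)
  duration <- t[n]
  eps <- strain_trajectory(t, duration, p$peak_strain_true,
                           gait$loading_fraction)
  epsdot <- strain_rate(eps, t)
  sigma <- p$E_true * eps + p$eta_true * eps * epsdot
  noise <- with_seed(derive_seed(seed, "measurement"), {
    list(stress = if (p$noise_cv > 0) rnorm(n, 0, p$noise_cv) else numeric(n),
         thick = if (gait$thickness_noise_sd > 0)
           rnorm(n, 0, gait$thickness_noise_sd) else numeric(n))
  })
  sigma_obs <- sigma * (1 + noise$stress)
  thickness <- p$h0_true * (1 - eps) + noise$thick
  out <- data.frame(frame = seq_len(n),
                    time_s = t,
                    thickness_mm = thickness,
                    force_N = stress_to_force_n(sigma_obs, gait$heel_area_cm2),
                    area_cm2 = rep(gait$heel_area_cm2, n))
  attr(out, "truth") <- list(strain = eps, strain_rate = epsdot,
                             stress_kpa = sigma, params = p)
  class(out) <- c("heel_trial", "data.frame")
  out
}

# 3x3 rotation about the x axis, degrees.
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' Render the 3D scene for a simulated trial
#'
#' Builds the geometry the thickness stage consumes: three non-collinear
#' marker-ball centers at height `ball_radius` above the plate, and a rigid
#' calcaneus shell (lower half of an ellipsoid, `n_cloud_points` points)
#' translated vertically each frame so that its minimum height above the
#' plate equals the trial's thickness channel exactly. An optional plate
#' tilt is applied rigidly to balls and cloud together, which leaves all
#' plane-cloud distances invariant.
#'
#' @param params cohort row that produced `trial` (used for the scene's
#'   random shell shape sub-stream).
#' @param trial the matching `heel_trial`.
#' @param gait a [gait_config()].
#' @param seed integer seed for the shell-shape draw; defaults to the trial
#'   seed.
#' @return An object of class `geometry_scene`: list with `ball_centers`
#'   (3 x 3), `ball_radius`, `plate_tilt_deg`, and `frames`, a list of
#'   `list(time, cloud)` per frame.
#' @export
render_scene <- function(params, trial, gait = gait_config(), seed = NULL) {
  p <- as.list(params)
  if (is.null(seed)) seed <- if (!is.null(p$trial_seed)) p$trial_seed else 1L
  stopifnot(is.data.frame(trial), nrow(trial) >= 1L)
  r <- gait$ball_radius
  centers <- rbind(c(-60, -60, r), c(120, -40, r), c(-40, 120, r))
  # Rigid shell: random directions on the lower unit hemisphere mapped onto
  # an ellipsoid roughly the size of a calcaneus (mm).
  semi <- c(30, 20, 15)
  cloud0 <- with_seed(derive_seed(seed, "scene"), {
    u <- matrix(rnorm(3L * gait$n_cloud_points), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    u[, 3L] <- -abs(u[, 3L])
    sweep(u, 2L, semi, `*`)
  })
  # Re-base so the lowest point sits exactly at z = 0; per-frame translation
  # by the thickness then makes min(z) equal the thickness channel exactly.
  cloud0[, 3L] <- cloud0[, 3L] - min(cloud0[, 3L])
  tilt <- gait$plate_tilt_deg
  R <- if (tilt != 0) rot_x(tilt) else NULL
  if (!is.null(R)) centers <- centers %*% t(R)
  frames <- lapply(seq_len(nrow(trial)), function(i) {
    cl <- cloud0
    cl[, 3L] <- cl[, 3L] + trial$thickness_mm[i]
    if (!is.null(R)) cl <- cl %*% t(R)
    list(time = trial$time_s[i], cloud = cl)
  })
  structure(list(ball_centers = centers, ball_radius = r,
                 plate_tilt_deg = tilt, frames = frames),
            class = "geometry_scene")
}

#' @export
print.geometry_scene <- function(x, ...) {
  cat(sprintf("Geometry scene: %d frames, %d-point cloud, ball radius %.2f mm, tilt %.2f deg\n",
              length(x$frames),
              if (length(x$frames)) nrow(x$frames[[1L]]$cloud) else 0L,
              x$ball_radius, x$plate_tilt_deg))
  invisible(x)
}
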