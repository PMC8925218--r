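# Strain/stress/strain-rate channels, nonlinear Kelvin-Voigt least-squares
# fit, hysteresis energy dissipation, and the per-trial analysis driver.
#
# Sign convention: compression is positive. The constitutive model is the
# nonlinear Kelvin-Voigt form sigma = E * eps + eta * eps * eps_dot, with
# sigma in kPa, eps dimensionless, eps_dot in 1/s, E in kPa, eta in kPa s.

#' Compressive strain from a thickness series
#'
#' Strain is the change in thickness divided by the primary thickness:
#' `eps_i = (h0 - thickness_i) / h0`, positive in compression, zero at the
#' contact frame by construction.
#'
#' @param thickness per-frame heel-pad thickness (mm).
#' @param h0 primary (unloaded) thickness (mm), > 0.
#' @return Dimensionless strain series.
#' @export
#' @examples
#' compute_strain(c(16, 12, 8), h0 = 16)
compute_strain <- function(thickness, h0) {
  assert_number(h0, "h0", lower = 0, strict_lower = TRUE)
  if (!is.numeric(thickness) || length(thickness) == 0L)
    stopf("'thickness' must be a non-empty numeric series", class = "empty_input_error")
  (h0 - thickness) / h0
}

#' Compressive stress from force and contact area
#'
#' `sigma_i = 10 * force_i[N] / area_i[cm^2]` in kPa. Area must be positive on
#' every in-contact frame (force > 0).
#'
#' @param force_n heel-ground force (N).
#' @param area_cm2 heel contact area (cm^2); scalar or per-frame.
#' @return Stress series in kPa.
#' @export
#' @examples
#' compute_stress(146.34, 10) # 146.34 kPa
compute_stress <- function(force_n, area_cm2) {
  if (!is.numeric(force_n) || length(force_n) == 0L)
    stopf("'force_n' must be a non-empty numeric series", class = "empty_input_error")
  area_cm2 <- rep_len(area_cm2, length(force_n))
  bad <- which(force_n > 0 & area_cm2 <= 0)
  if (length(bad))
    stopf("non-positive contact area on in-contact frame %d", bad[1L],
          class = "unit_error")
  out <- force_to_stress_kpa(force_n, area_cm2)
  out[force_n == 0 & area_cm2 <= 0] <- 0
  out
}

#' Strain rate: tangent of the strain-time curve
#'
#' Central finite differences on interior frames, one-sided differences at
#' the endpoints. Optional local-polynomial (Savitzky-Golay) smoothing of the
#' strain channel before differencing.
#'
#' @param strain dimensionless strain series (>= 3 frames).
#' @param time time stamps in s, strictly increasing.
#' @param smoothing logical; apply local-polynomial smoothing first.
#' @param window odd smoothing window length in frames.
#' @param degree polynomial degree of the smoother.
#' @return Strain rate in 1/s.
#' @export
strain_rate <- function(strain, time, smoothing = FALSE, window = 5L,
                        degree = 2L) {
  if (length(strain) < 3L)
    stopf("at least 3 frames are required to differentiate", class = "invalid_input_error")
  if (length(time) != length(strain) || any(diff(time) <= 0))
    stopf("'time' must be strictly increasing and match 'strain' in length",
          class = "invalid_input_error")
  if (isTRUE(smoothing)) {
    if (window %% 2L != 1L || window <= degree)
      stopf("smoothing window must be odd and exceed the polynomial degree",
            class = "invalid_config_error")
    strain <- signal::sgolayfilt(strain, p = degree, n = window)
  }
  pracma::gradient(strain, time)
}

#' Fit the nonlinear Kelvin-Voigt model by least squares
#'
#' Solves `(E, eta) = argmin sum_i (sigma_i - E*eps_i - eta*eps_i*epsdot_i)^2`
#' in closed form via QR orthogonal factorization of the two-column regressor
#' matrix `[eps, eps*epsdot]`. The model has no intercept and the fit is
#' unconstrained: negative estimates set `negative_param_flag` and are never
#' clipped (clipping would bias cohort medians).
#'
#' @param stress stress series (kPa).
#' @param strain strain series (dimensionless).
#' @param strain_rate strain-rate series (1/s).
#' @return An object of class `visco_fit`: list with `E` (kPa), `eta` (kPa s),
#'   `rss` (kPa^2), `r_squared` (1 - rss / centered total SS), `n_frames`,
#'   `negative_param_flag`, and per-frame `fitted` and `residuals`.
#' @export
fit_kelvin_voigt <- function(stress, strain, strain_rate) {
  n <- length(stress)
  if (n < 3L || length(strain) != n || length(strain_rate) != n)
    stopf("stress, strain and strain_rate must share length >= 3",
          class = "invalid_input_error")
  X <- cbind(elastic = strain, viscous = strain * strain_rate)
  qrx <- qr(X)
  if (qrx$rank < 2L) {
    degen <- if (all(abs(X[, "viscous"]) < .Machine$double.eps * max(1, abs(X))))
      "strain*strain_rate (viscous)" else "strain (elastic)"
    stopf("Kelvin-Voigt regressors are rank-deficient; degenerate column: %s",
          degen, class = "unidentifiable_model_error")
  }
  beta <- qr.coef(qrx, stress)
  fitted <- drop(X %*% beta)
  res <- stress - fitted
  rss <- sum(res^2)
  tss <- sum((stress - mean(stress))^2)
  structure(list(
    E = unname(beta[1L]), eta = unname(beta[2L]),
    rss = rss,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n_frames = n,
    negative_param_flag = beta[1L] < 0 || beta[2L] < 0,
    fitted = fitted, residuals = res
  ), class = "visco_fit")
}

#' @export
print.visco_fit <- function(x, ...) {
  cat("Nonlinear Kelvin-Voigt fit (sigma = E*eps + eta*eps*eps_dot)\n")
  cat(sprintf("  E   = %.4f kPa\n  eta = %.4f kPa s\n", x$E, x$eta))
  cat(sprintf("  n = %d frames, RSS = %.4g kPa^2, R^2 = %.5f\n",
              x$n_frames, x$rss, x$r_squared))
  if (isTRUE(x$negative_param_flag))
    cat("  warning: at least one estimate is negative\n")
  invisible(x)
}

#' Split a strain cycle into loading and unloading branches
#'
#' The split is at the first frame attaining the global strain maximum; that
#' frame belongs to both branches so the hysteresis loop stays contiguous.
#' A monotone series raises a degenerate-loop warning (unloading length 1).
#'
#' @param strain strain series.
#' @return List with integer index vectors `loading` and `unloading`.
#' @export
split_loading_unloading <- function(strain) {
  n <- length(strain)
  if (n == 0L) stopf("strain series is empty", class = "empty_input_error")
  imax <- which.max(strain)
  if (imax == n)
    warning("strain series is monotone non-decreasing; degenerate loop with unloading branch of length 1",
            call. = FALSE)
  list(loading = seq_len(imax), unloading = seq.int(imax, n))
}

#' Hysteresis energy dissipation and energy dissipation rate
#'
#' The energy dissipated per cycle (per unit volume) is the area enclosed by
#' the stress-strain loop, computed with the shoelace formula on the closed
#' polygon of `(strain, stress)` vertices (the polygon is closed by the chord
#' from the last to the first point when the cycle does not return exactly to
#' its start). The loading energy is the trapezoid-rule integral of stress
#' over strain along the loading branch. EDR = 100 * |loop area| / loading
#' area, in percent.
#'
#' @param stress stress series (kPa).
#' @param strain strain series (dimensionless), one loading-unloading cycle.
#' @return List with `dissipation` (kPa), `loading_area` (kPa), `edr` (%),
#'   and `out_of_range` (TRUE when EDR falls outside `[0, 100]`; flagged, not
#'   clamped).
#' @export
#' @examples
#' s <- seq(0, 0.5, length.out = 6)
#' energy_dissipation_rate(c(200 * s, 200 * rev(s) - 20), c(s, rev(s)))
energy_dissipation_rate <- function(stress, strain) {
  n <- length(strain)
  if (n < 3L || length(stress) != n)
    stopf("stress and strain must share length >= 3", class = "invalid_input_error")
  sp <- suppressWarnings(split_loading_unloading(strain))
  li <- sp$loading
  loading_area <- pracma::trapz(strain[li], stress[li])
  if (!is.finite(loading_area) || loading_area <= 0)
    stopf("loading-branch area is not positive (%.4g kPa); degenerate loading curve",
          loading_area, class = "degenerate_curve_error")
  xn <- c(strain[-1L], strain[1L])
  yn <- c(stress[-1L], stress[1L])
  loop_area <- 0.5 * abs(sum(strain * yn - xn * stress))
  edr <- 100 * loop_area / loading_area
  list(dissipation = loop_area, loading_area = loading_area, edr = edr,
       out_of_range = edr < 0 || edr > 100)
}

#' Peak strain and peak stress
#'
#' Channel maxima located independently (their argmax frames need not
#' coincide), with the frame indices of both maxima.
#'
#' @param stress stress series (kPa).
#' @param strain strain series.
#' @return List `peak_strain`, `peak_stress`, `peak_strain_frame`,
#'   `peak_stress_frame`.
#' @export
peak_values <- function(stress, strain) {
  if (length(strain) == 0L || length(stress) == 0L)
    stopf("series are empty", class = "empty_input_error")
  list(peak_strain = max(strain), peak_stress = max(stress),
       peak_strain_frame = which.max(strain),
       peak_stress_frame = which.max(stress))
}

#' Analysis-stage configuration
#'
#' @param contact_force_threshold force threshold (N) for contact detection.
#' @param min_consecutive consecutive frames required at threshold.
#' @param baseline_force force level (N) treated as no load when backtracking
#'   to the contact onset.
#' @param smoothing,smoothing_window,smoothing_degree strain-rate smoothing
#'   controls (see [strain_rate()]); smoothing is off by default.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(contact_force_threshold = 10,
                            min_consecutive = 1L,
                            baseline_force = 0,
                            smoothing = FALSE,
                            smoothing_window = 5L,
                            smoothing_degree = 2L) {
  assert_number(contact_force_threshold, "contact_force_threshold",
                lower = 0, strict_lower = TRUE)
  assert_number(min_consecutive, "min_consecutive", lower = 1)
  assert_number(baseline_force, "baseline_force", lower = 0)
  structure(list(contact_force_threshold = contact_force_threshold,
                 min_consecutive = as.integer(min_consecutive),
                 baseline_force = baseline_force,
                 smoothing = isTRUE(smoothing),
                 smoothing_window = as.integer(smoothing_window),
                 smoothing_degree = as.integer(smoothing_degree)),
            class = "analysis_config")
}

# Run expr as a named pipeline stage; errors are re-thrown tagged with the
# failing stage so per-trial failures are attributable.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage '%s': %s", stage, conditionMessage(e)),
                        class = c("heelpad_stage_error", class(e)),
                        stage = stage))
  })
}

#' Analyze one stance-phase trial into heel-pad properties
#'
#' Runs the full per-trial pipeline: contact detection (threshold crossing
#' backtracked to load onset), primary thickness, strain / stress /
#' strain-rate channels on the stance window, peak values, Kelvin-Voigt
#' least-squares fit, and hysteresis energy dissipation rate. The thickness
#' channel comes either from the trial table or, when `scene` is given, from
#' per-frame point-cloud geometry via [heel_pad_thickness()].
#'
#' @param trial a `heel_trial` data frame (columns `time_s`, `thickness_mm`,
#'   `force_N`, `area_cm2`), e.g. from [simulate_stance()] or
#'   [read_trial_csv()].
#' @param config an [analysis_config()].
#' @param scene optional [geometry_scene] matching the trial frame-for-frame;
#'   when supplied the thickness channel is recomputed from geometry.
#' @param plane optional `ref_plane`; derived from the scene when NULL.
#' @return An object of class `heel_properties`: list with
#'   `primary_thickness` (mm), `peak_strain`, `peak_stress` (kPa),
#'   `elastic_modulus` (kPa), `viscous_modulus` (kPa s), `edr` (%), and a
#'   `diagnostics` sublist (fit object, contact/onset indices, loop areas,
#'   flags).
#' @export
analyze_trial <- function(trial, config = analysis_config(), scene = NULL,
                          plane = NULL) {
  stopifnot(is.data.frame(trial))
  force <- trial$force_N
  onset <- run_stage("contact", contact_onset_frame(
    force, config$contact_force_threshold, config$min_consecutive,
    config$baseline_force))
  thickness <- run_stage("thickness", {
    if (is.null(scene)) {
      trial$thickness_mm
    } else {
      if (is.null(plane)) plane <- plane_from_balls(scene$ball_centers,
                                                    scene$ball_radius)
      vapply(scene$frames,
             function(f) heel_pad_thickness(f$cloud, plane, scene$ball_radius),
             numeric(1))
    }
  })
  h0 <- run_stage("primary_thickness", primary_thickness(thickness, onset))
  idx <- seq.int(onset, nrow(trial))
  if (length(idx) < 3L)
    stopf("stage 'crop': fewer than 3 stance frames after contact",
          class = "degenerate_trajectory_error")
  eps <- run_stage("strain", compute_strain(thickness[idx], h0))
  sig <- run_stage("stress", compute_stress(force[idx], trial$area_cm2[idx]))
  epsdot <- run_stage("strain_rate", strain_rate(
    eps, trial$time_s[idx], smoothing = config$smoothing,
    window = config$smoothing_window, degree = config$smoothing_degree))
  pk <- run_stage("peaks", peak_values(sig, eps))
  fit <- run_stage("fit", fit_kelvin_voigt(sig, eps, epsdot))
  ed <- run_stage("edr", energy_dissipation_rate(sig, eps))
  structure(list(
    primary_thickness = h0,
    peak_strain = pk$peak_strain,
    peak_stress = pk$peak_stress,
    elastic_modulus = fit$E,
    viscous_modulus = fit$eta,
    edr = ed$edr,
    diagnostics = list(fit = fit, contact_onset = onset,
                       peak_strain_frame = pk$peak_strain_frame,
                       peak_stress_frame = pk$peak_stress_frame,
                       dissipation = ed$dissipation,
                       loading_area = ed$loading_area,
                       edr_out_of_range = ed$out_of_range,
                       negative_param_flag = fit$negative_param_flag,
                       strain = eps, stress = sig, strain_rate = epsdot)
  ), class = "heel_properties")
}

#' @export
print.heel_properties <- function(x, ...) {
  cat("Heel-pad properties\n")
  cat(sprintf("  primary thickness: %8.3f mm\n", x$primary_thickness))
  cat(sprintf("  peak strain      : %8.4f\n", x$peak_strain))
  cat(sprintf("  peak stress      : %8.3f kPa\n", x$peak_stress))
  cat(sprintf("  elastic modulus E: %8.3f kPa\n", x$elastic_modulus))
  cat(sprintf("  viscous modulus  : %8.3f kPa s\n", x$viscous_modulus))
  cat(sprintf("  EDR              : %8.3f %%\n", x$edr))
  invisible(x)
}

#' @export
as.data.frame.heel_properties <- function(x, ...) {
  data.frame(primary_thickness = x$primary_thickness,
             peak_strain = x$peak_strain,
             peak_stress = x$peak_stress,
             elastic_modulus = x$elastic_modulus,
             viscous_modulus = x$viscous_modulus,
             edr = x$edr)
}
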