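# Strain/stress channels, Kelvin-Voigt fitting, hysteresis, trial analysis.

test_that("strain is thickness change over primary thickness", {
  expect_equal(compute_strain(16, 16), 0)
  expect_equal(compute_strain(8, 16), 0.5)
  expect_equal(compute_strain(5.03685, 15.99), 0.685)
  expect_error(compute_strain(c(1, 2), 0), class = "invalid_config_error")
})

test_that("stress converts N over cm^2 to kPa", {
  expect_equal(compute_stress(0, 10), 0)
  expect_equal(compute_stress(146.34, 10), 146.34)
  expect_equal(compute_stress(50, 5), 100)
  err <- tryCatch(compute_stress(c(10, 20), c(10, 0)), error = function(e) e)
  expect_s3_class(err, "unit_error")
  expect_match(conditionMessage(err), "frame 2")
})

test_that("strain rate is exact on linear and quadratic strain histories", {
  t <- seq(0, 0.2, by = 0.02)
  expect_equal(strain_rate(rep(0.3, 11), t), rep(0, 11))
  expect_equal(strain_rate(0.5 * t, t), rep(0.5, 11), tolerance = 1e-12)
  # central difference of t^2 is exact: ((t+d)^2 - (t-d)^2) / 2d = 2t
  d <- strain_rate(t^2, t)
  expect_equal(d[6], 2 * t[6], tolerance = 1e-12)
  expect_equal(d[2:10], 2 * t[2:10], tolerance = 1e-12)
  expect_error(strain_rate(t, rev(t)), class = "invalid_input_error")
  expect_error(strain_rate(c(0, 1), c(0, 1)), class = "invalid_input_error")
})

test_that("Kelvin-Voigt fit recovers a pure elastic law and flags negatives", {
  t <- seq(0, 0.6, by = 0.02)
  eps <- 0.6 * sin(pi * t / 0.6)^2
  epsdot <- strain_rate(eps, t)
  fit <- fit_kelvin_voigt(100 * eps, eps, epsdot)
  expect_equal(fit$E, 100, tolerance = 1e-9)
  expect_equal(fit$eta, 0, tolerance = 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-9)
  expect_false(fit$negative_param_flag)
  fit2 <- fit_kelvin_voigt(100 * eps - 30 * eps * epsdot, eps, epsdot)
  expect_true(fit2$negative_param_flag)
  expect_equal(fit2$eta, -30, tolerance = 1e-8)
})

test_that("fit equals the independent normal-equations oracle", {
  # fixed 5-frame toy dataset
  eps <- c(0.05, 0.2, 0.45, 0.3, 0.1)
  epsdot <- c(2.5, 3.1, 0.2, -2.8, -3.3)
  sig <- c(12, 45, 90, 40, 9)
  fit <- fit_kelvin_voigt(sig, eps, epsdot)
  ref <- oracle_normal_equations(sig, eps, epsdot)
  expect_equal(fit$E, ref[1], tolerance = 1e-9)
  expect_equal(fit$eta, ref[2], tolerance = 1e-9)
  # property: equality on random instances
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    eps <- runif(n, 0.01, 0.7)
    epsdot <- rnorm(n, 0, 3)
    sig <- runif(1, 50, 300) * eps + runif(1, 0, 80) * eps * epsdot +
      rnorm(n, 0, 5)
    fit <- fit_kelvin_voigt(sig, eps, epsdot)
    ref <- oracle_normal_equations(sig, eps, epsdot)
    expect_equal(c(fit$E, fit$eta), unname(ref), tolerance = 1e-9)
    expect_lte(fit$r_squared, 1)
  }
})

test_that("rank-deficient regressors raise an unidentifiable-model error", {
  eps <- c(0.1, 0.2, 0.3, 0.4)
  err <- tryCatch(fit_kelvin_voigt(10 * eps, eps, rep(0, 4)),
                  error = function(e) e)
  expect_s3_class(err, "unidentifiable_model_error")
  expect_match(conditionMessage(err), "viscous")
})

test_that("loading/unloading split is at the first global strain maximum", {
  sp <- split_loading_unloading(c(0, 0.3, 0.7, 0.4, 0))
  expect_identical(sp$loading, 1:3)
  expect_identical(sp$unloading, 3:5)
  # plateaued maximum: first occurrence wins
  sp2 <- split_loading_unloading(c(0, 0.7, 0.7, 0))
  expect_identical(sp2$loading, 1:2)
  expect_identical(sp2$unloading, 2:4)
  expect_warning(sp3 <- split_loading_unloading(c(0, 0.2, 0.5)), "monotone")
  expect_identical(sp3$unloading, 3:3)
})

test_that("parallelogram loop gives EDR 40% and retraced loops give 0", {
  s <- seq(0, 0.5, length.out = 6)
  ed <- energy_dissipation_rate(c(200 * s, 200 * rev(s) - 20), c(s, rev(s)))
  expect_equal(ed$dissipation, 10, tolerance = 1e-12)
  expect_equal(ed$loading_area, 25, tolerance = 1e-12)
  expect_equal(ed$edr, 40, tolerance = 1e-12)
  ed0 <- energy_dissipation_rate(c(200 * s, 200 * rev(s)), c(s, rev(s)))
  expect_equal(ed0$edr, 0, tolerance = 1e-12)
  expect_error(energy_dissipation_rate(c(0, -1, 0), c(0, 0.5, 0)),
               class = "degenerate_curve_error")
})

test_that("EDR matches a dense-quadrature oracle for a Kelvin-Voigt cycle", {
  E <- 192.55; eta <- 43.9; peak <- 0.685; T <- 0.6
  eps_fun <- function(t) peak * sin(pi * t / T)^2
  epsdot_fun <- function(t) peak * pi / T * sin(2 * pi * t / T)
  sig_fun <- function(t) E * eps_fun(t) + eta * eps_fun(t) * epsdot_fun(t)
  ref <- oracle_loop_areas_dense(eps_fun, sig_fun, T)
  t <- seq(0, T, length.out = 301)
  ed <- energy_dissipation_rate(sig_fun(t), eps_fun(t))
  expect_equal(ed$edr, ref$edr, tolerance = 0.005)
  expect_equal(ed$dissipation, ref$loop, tolerance = 0.005 * ref$loop)
})

test_that("EDR increases with the viscous modulus at fixed trajectory", {
  T <- 0.6; peak <- 0.6
  t <- seq(0, T, by = 0.02)
  eps <- peak * sin(pi * t / T)^2
  epsdot <- strain_rate(eps, t)
  edrs <- vapply(c(0, 5, 15, 30, 60), function(eta) {
    energy_dissipation_rate(180 * eps + eta * eps * epsdot, eps)$edr
  }, numeric(1))
  expect_true(all(diff(edrs) > 0))
  expect_true(all(edrs >= 0 & edrs <= 100))
})

test_that("scaling stress scales moduli and dissipation, leaves EDR and peaks invariant", {
  p <- list(h0_true = 15, E_true = 180, eta_true = 35,
            peak_strain_true = 0.6, stance_duration = 0.6, noise_cv = 0)
  tr <- simulate_stance(p, noiseless_gait_config(), seed = 2)
  eps <- 1 - tr$thickness_mm / p$h0_true
  sig <- 10 * tr$force_N / tr$area_cm2
  epsdot <- strain_rate(eps, tr$time_s)
  for (cc in c(0.5, 3)) {
    fit1 <- fit_kelvin_voigt(sig, eps, epsdot)
    fit2 <- fit_kelvin_voigt(cc * sig, eps, epsdot)
    expect_equal(fit2$E, cc * fit1$E, tolerance = 1e-9)
    expect_equal(fit2$eta, cc * fit1$eta, tolerance = 1e-9)
    ed1 <- energy_dissipation_rate(sig, eps)
    ed2 <- energy_dissipation_rate(cc * sig, eps)
    expect_equal(ed2$dissipation, cc * ed1$dissipation, tolerance = 1e-9)
    expect_equal(ed2$edr, ed1$edr, tolerance = 1e-9)
    expect_equal(peak_values(cc * sig, eps)$peak_strain,
                 peak_values(sig, eps)$peak_strain)
  }
})

test_that("peak strain and peak stress are independent channel maxima", {
  pk <- peak_values(c(10, 162.95, 150), c(0.1, 0.6, 0.700))
  expect_equal(pk$peak_strain, 0.700)
  expect_equal(pk$peak_stress, 162.95)
  expect_identical(pk$peak_strain_frame, 3L)
  expect_identical(pk$peak_stress_frame, 2L)
  # monotone channels peak at the last frame
  pk2 <- peak_values(1:5, (1:5) / 10)
  expect_identical(pk2$peak_stress_frame, 5L)
  # of two local stress maxima the larger wins
  expect_equal(peak_values(c(0, 150, 100, 140, 0), c(0, 0.3, 0.5, 0.4, 0))$peak_stress,
               150)
})

test_that("analyze_trial composes the stages and tags failures", {
  p <- list(h0_true = 15.99, E_true = 192.55, eta_true = 43.9,
            peak_strain_true = 0.685, stance_duration = 0.6, noise_cv = 0)
  pr <- analyze_params(p)
  expect_equal(pr$elastic_modulus, p$E_true, tolerance = 1e-6 * p$E_true)
  expect_equal(pr$viscous_modulus, p$eta_true, tolerance = 1e-6 * p$eta_true)
  expect_identical(pr$primary_thickness, p$h0_true)
  # pure elastic: zero viscous modulus and zero EDR
  pe <- analyze_params(list(h0_true = 16, E_true = 150, eta_true = 0,
                            peak_strain_true = 0.5, stance_duration = 0.6,
                            noise_cv = 0))
  expect_equal(pe$viscous_modulus, 0, tolerance = 1e-8)
  expect_equal(pe$edr, 0, tolerance = 1e-6)
  # all-zero force fails in the contact stage
  tr <- simulate_stance(p, noiseless_gait_config(), seed = 1)
  tr$force_N <- 0
  err <- tryCatch(analyze_trial(tr), error = function(e) e)
  expect_s3_class(err, "heelpad_stage_error")
  expect_identical(err$stage, "contact")
})

test_that("geometry-derived analysis matches thickness-channel analysis", {
  cfg <- noiseless_cohort_config(n_subjects = 1)
  coh <- sample_cohort(cfg, seed = 23)
  g <- noiseless_gait_config(n_cloud_points = 150)
  tr <- simulate_stance(coh[1, ], g)
  sc <- render_scene(coh[1, ], tr, g)
  pr_t <- analyze_trial(tr)
  pr_g <- analyze_trial(tr, scene = sc)
  for (f in c("primary_thickness", "peak_strain", "peak_stress",
              "elastic_modulus", "viscous_modulus", "edr"))
    expect_equal(pr_g[[f]], pr_t[[f]], tolerance = 1e-6)
})
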