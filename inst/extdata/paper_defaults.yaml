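# Default run configuration: cohort calibration targets from a published
# in-vivo heel-pad study of healthy adults (see the package vignette for the
# calibration arithmetic). Medians are per loading condition; post-loading
# shifts are multiplicative.
seed: 1
cohort:
  n_subjects: 10
  age_range: [23, 72]          # years
  bmi_mean: 24.6               # kg/m^2
  bmi_sd: 3.5
  bmi_range: [19.2, 31.9]
  h0_median: 15.99             # mm, time-zero cohort median
  h0_age_slope: -0.0717        # mm per year; yields R(age, h0) ~ -0.5
  h0_subject_sd: 1.72
  h0_side_sd: 0.3
  h0_post_multiplier: 0.98311445 # 15.72 / 15.99
  h0_condition_sd: 0.05
  elastic_median: 192.55       # kPa
  log_elastic_subject_sd: 0.15
  log_elastic_side_sd: 0.05
  elastic_post_multiplier: 1.0 # elastic modulus unchanged by loading history
  log_elastic_condition_sd: 0.06
  eta_median: 43.9             # kPa s, time-zero
  eta_elastic_coupling: 0.29   # yields R(E, eta) ~ 0.78
  eta_age_coupling: 0.12       # yields R(age, eta) ~ 0.36
  log_eta_side_sd: 0.06
  eta_post_multiplier: 0.46400911 # 20.37 / 43.9: viscous modulus ~halved
  log_eta_condition_sd: 0.08
  peak_strain_median: 0.685
  peak_strain_subject_sd: 0.015
  peak_strain_side_sd: 0.005
  peak_strain_post_shift: 0.005
  peak_strain_condition_sd: 0.005
  stance_duration_mean: 0.6    # s, typical stance at ~1 m/s
  stance_duration_sd: 0.04
  noise_cv: 0.01               # multiplicative stress measurement noise
gait:
  frame_rate: 50               # Hz
  gait_velocity: 1.0           # m/s, documentation only
  trajectory_shape: asymmetric_cosine
  loading_fraction: 0.45
  ball_radius: 5               # mm
  n_cloud_points: 500
  heel_area_cm2: 10
  thickness_noise_sd: 0.05     # mm
  plate_tilt_deg: 0
analysis:
  contact_force_threshold: 10  # N
  min_consecutive: 1
  baseline_force: 0
  smoothing: false
  smoothing_window: 5
  smoothing_degree: 2
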