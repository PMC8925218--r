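---
title: "Methods: heel-pad viscoelastic property estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heel-pad viscoelastic property estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heelpad)
```

## The measurement problem

The heel fat pad is the adipose cushion between the calcaneus and the skin;
it dissipates impact energy at heel strike, and its viscous behaviour
degrades in conditions such as diabetes before its stiffness does. In vivo,
its material properties can be estimated during walking by combining two
synchronized data streams at 50 Hz over the stance phase:

* a geometric stream giving the pad **thickness** per frame — the calcaneus
  is tracked as a 3D point cloud, the force plate is located by three steel
  marker balls resting on it, and thickness is the minimum distance from the
  calcaneus to the ball-center plane plus the ball radius (the plane through
  the centers of balls of radius $r$ lying on the plate is parallel to the
  plate at height $r$);
* a load stream giving the vertical heel–ground **force** and the heel
  **contact area**, from a pressure plate.

From these, six per-heel endpoints are computed: primary thickness
$h_0$, peak strain, peak stress, elastic modulus $E$, viscous modulus
$\eta$, and the energy dissipation rate (EDR).

## Model and derived channels

With $h_0$ the thickness at initial contact, the derived channels are

$$\varepsilon_i = \frac{h_0 - h_i}{h_0}, \qquad
  \sigma_i = \frac{10\,F_i[\mathrm{N}]}{A_i[\mathrm{cm^2}]}\ \mathrm{kPa},
  \qquad
  \dot\varepsilon_i = \left.\frac{d\varepsilon}{dt}\right|_{t_i},$$

with compression positive. The constitutive model is the nonlinear
Kelvin–Voigt form in which the dashpot term is scaled by the strain:

$$\sigma = E\,\varepsilon + \eta\,\varepsilon\,\dot\varepsilon ,$$

$E$ in kPa, $\eta$ in kPa·s. Because the model is linear in $(E, \eta)$
given the channels, the fit is ordinary least squares without intercept on
the regressors $[\varepsilon,\ \varepsilon\dot\varepsilon]$, solved by QR
factorization (`fit_kelvin_voigt()`). The fit is unconstrained; negative
estimates are flagged, never clipped, because clipping at zero would bias
cohort medians upward. Rank deficiency (e.g. $\varepsilon\dot\varepsilon
\equiv 0$) raises an unidentifiable-model error naming the degenerate
column.

**Strain rate.** The strain rate is *defined* as the tangent of the sampled
strain–time curve: central differences on interior frames, one-sided at the
endpoints (`pracma::gradient`). The forward simulator uses the same
definition when it evaluates the constitutive formula, so the noiseless
round trip is an exact algebraic identity rather than an
$O(\Delta t^2)$ approximation; this is what makes machine-precision
parameter recovery a meaningful invariant to test. Optional
Savitzky–Golay smoothing (window 5 frames, degree 2; off by default) is
available for noisy thickness channels.

**Hysteresis and EDR.** The loading/unloading split is at the first frame
attaining the global strain maximum (ties broken by first occurrence; a
monotone series degenerates to an unloading branch of length 1 with a
warning). Energy dissipation is the area of the closed stress–strain
polygon by the shoelace formula — the polygon is closed by the chord from
the last to the first vertex when a noisy cycle does not return exactly to
its origin. The loading energy is the trapezoid-rule integral of
$\sigma\,d\varepsilon$ along the loading branch, and
$\mathrm{EDR} = 100\,|A_{loop}|/A_{loading}$ percent. Values outside
$[0, 100]$ are flagged, not clamped. Peak strain and peak stress are
independent channel maxima with their argmax frames reported, since the two
maxima need not coincide in time.

**Contact and primary thickness.** Contact is detected as the first run of
`min_consecutive` frames with force at or above a threshold (default 10 N,
1 frame). The analysis then backtracks through the contiguous
above-baseline run to the last zero-load frame and takes that as the onset
of skin–plate contact: the threshold rejects baseline noise, the walk-back
removes the threshold's detection lag, and the thickness at the onset frame
is the primary thickness $h_0$. Without the walk-back, $h_0$ would be read
one or more frames into loading, re-zeroing the strain at a few-percent
compression and biasing $E$ and $\eta$ by the same order.

**Units and geometry conventions.** All geometry is in mm; the only unit
conversion (N over cm² to kPa, factor 10) is centralized. Point–plane
distances are signed along the plate-to-foot normal, so cloud points that
numerically penetrate the plate contribute negative distances and are
reported as such rather than silently inflating the minimum thickness.

## The synthetic cohort generator

No individual-level data are distributed with this problem, so the
generator is the package's study population: it emulates the statistical
structure of a published in-vivo healthy-adult cohort (10 subjects, ages
23–72, both heels, measured at *time zero* after an hour of rest and
*post-loading* after 15 min of sustained standing), and its defaults are
frozen as the package's study conditions.

Per heel, a stance trial is simulated by (i) a cosine-up / cosine-down
strain trajectory over the stance duration (loading fraction 0.45 of
stance, reflecting a single loading–unloading cycle with slightly faster
loading), (ii) the forward constitutive formula on the sampled grid, and
(iii) the observable map $h_i = h_0(1-\varepsilon_i)$,
$F_i = \sigma_i A/10$ with a constant heel area $A = 10\ \mathrm{cm^2}$.
Measurement noise is multiplicative Gaussian on stress (CV 0.01 by
default — a pressure-plate measurement-chain model) and optional additive
Gaussian on thickness (SD 0.05 mm). The published source reports no stance
duration, heel area, or noise characterization; these defaults are the
package's own choices of realistic values and are configurable.

Cohort structure is induced by latent linear regressions. With age
$\sim U(23, 72)$ (mean 47.5, SD 14.1) and $z_a$ the standardized age:

* $h_0 = 15.99 - 0.0717\,(\mathrm{age} - 47.5) + N(0, 1.72^2)_{subject}
  + N(0, 0.3^2)_{side}$ mm, giving
  $R(\mathrm{age}, h_0) = -0.0717\cdot 14.1 / \sqrt{1.01 + 2.96 + 0.09}
  \approx -0.50$;
* $\log E = \log 192.55 + 0.15\,z_E + N(0, 0.05^2)_{side}
  + N(0, 0.06^2)_{condition}$ with $z_E \sim N(0,1)$ a subject latent;
* $\log \eta = \log 43.9 + 0.29\,z_E + 0.12\,z_a + N(0, 0.06^2)_{side}
  + N(0, 0.08^2)_{condition}$, giving
  $R(E, \eta) \approx (0.29 \cdot 0.15)/(0.169 \cdot 0.33) \approx 0.78$
  and $R(\mathrm{age}, \eta) \approx 0.36$.

The attenuation by side- and condition-level noise caps the attainable
$E$–$\eta$ correlation near 0.80 once both moduli carry realistic
test–retest variability, so the generator reproduces the reported strong
positive coupling approximately rather than exactly; the weaker age–$\eta$
coupling was traded off in favour of it.

Post-loading shifts are multiplicative: $\eta$ is scaled by
$20.37/43.9 \approx 0.464$ (the viscous modulus roughly halves after
sustained loading), $h_0$ by $15.72/15.99$, peak strain shifted by
$+0.005$, and $E$ by 1.0 — the elastic modulus is modelled as a tissue
property unaffected by loading history, consistent with the nonsignificant
difference reported in vivo. Every random draw flows from one master seed
through deterministic per-(subject, side, condition) sub-streams, so
cohorts are reproducible and heels are independent given the latents.

The rendered 3D scenes (three ball centers at height $r$, a rigid
ellipsoidal calcaneus shell translated per frame so its minimum plate
height equals the thickness channel exactly) exercise the geometry path
end to end; scene-based and channel-based analyses agree to $10^{-6}$.

**What the generator does not emulate.** Fluoroscopic projection,
registration error (the dominant real-world thickness error source),
spatially resolved pressure maps (area is a scalar), footwear and gait-style
variation, and any intra-subject correlation beyond the shared latents.
Passing tests therefore demonstrate correctness of the estimation pipeline
under the stated noise model, not robustness to registration artifacts.

## Statistics layer

Summaries are medians with min–max ranges per property, side (left, right,
combined) and condition, with empty cells marked absent. Correlation
matrices use Pearson's $R$ with two-sided $p$-values from the $t$
transform on $n-2$ degrees of freedom; heels are pooled as observations by
default (matching the source tables), with a per-subject-mean option
because pooled heels are not independent — either choice is a documented
compromise. Condition comparisons use the paired Wilcoxon signed-rank test
on heels matched by (subject, side): zero differences dropped, exact null
distribution when $n_{\mathrm{eff}} \le 25$ with untied magnitudes, normal
approximation with continuity and tie corrections otherwise
(`stats::wilcox.test` underneath); all-tie comparisons are reported as
$p = 1$. No multiple-testing correction is applied, matching the source
analysis. Note that with 20 pairs the exact two-sided test's attainable
size just below 0.05 is 0.0484, so under a true null about 4.8% of
replicate cohorts show $p \le 0.05$ by construction of the test's discrete
null — relevant when interpreting replicate-fraction summaries of the
elastic-modulus comparison.

## Numerical choices and degenerate inputs

* Least squares via QR, not the normal equations; the normal-equations
  solution exists in the test suite as an independent oracle only.
* $R^2 = 1 - \mathrm{RSS}/\sum(\sigma - \bar\sigma)^2$; undefined (NA) for
  constant stress.
* Trajectories shorter than 3 frames, empty clouds, collinear ball centers
  (reported with the triangle's minimum altitude), all-zero force (no
  contact), zero area on in-contact frames, and monotone strain series all
  raise typed errors; per-trial pipeline failures are tagged with the
  failing stage and isolated in cohort runs.
* Problem sizes used in the checked examples: 31-frame trials (50 Hz ×
  0.6 s), 10-subject cohorts (40 heels) for round trips, 500 replicate
  trials for noise bias, 100 replicate cohorts for the paired-comparison
  fractions, 200-subject cohorts for correlation calibration.

## Known limitations

* The EDR of the default simulated trials (≈ 60%) is an emergent quantity,
  not a calibration target: with the calibrated moduli and a 0.6 s stance,
  the viscous stress share — and hence the loop area — is larger than in
  published in-vivo loops (≈ 20–25%), whose strain trajectories evolve more
  slowly near peak compression than a cosine. Only the directly calibrated
  endpoints (h₀, E, η, peak strain) should be compared to published
  medians.
* Peak stress emerges near 160–175 kPa rather than the published
  ≈ 146 kPa median, for the same reason (viscous overshoot during loading).
* The estimator inherits the identifiability limits of the model: if the
  strain-rate channel is nearly proportional to a constant over the stance
  window, $\eta$ is poorly determined; the rank check catches only the
  exact case.
* Left and right heels of one subject are treated as independent
  observations in the correlation layer, as in the source tables; a
  mixed-effects treatment of the nesting is out of scope.
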