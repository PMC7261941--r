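---
title: "Involuntary arm impedance from feedback jerk isolation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Involuntary arm impedance from feedback jerk isolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(armfji)
```

This vignette is the package's own account of the science it implements: the
mechanical and neuromuscular models, the estimation procedure and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## 1. The impedance model

The arm is a planar two-link chain (shoulder angle $q_1$, elbow angle
$q_2 \in (0,\pi)$, Cartesian origin at the shoulder), constrained to the
horizontal plane so gravity drops out:

$$\tau_{int} + \tau_{ext} = M(q)\,\ddot q + C(q,\dot q)\,\dot q .$$

Planar rigid-body torques are linear in exactly three **base inertial
parameters**,
$\bar\pi = \bigl(I_1 + m_2 l_1^2,\; I_2,\; m_2 l_{c2} l_1\bigr)$
(with $I_i$ the link inertias about the proximal joint via the parallel-axis
theorem), through a $2\times 3$ base regressor $\bar Y(q,\dot q,\ddot q)$
— `base_regressor()` and `mass_coriolis()` are two independent codings of
the same dynamics and are cross-checked to $10^{-9}$ in the test suite.

Within an estimation window short enough to exclude voluntary reactions
($T_{est} = \delta_v = 115$ ms), the involuntary feedback torque is
linearized about the unperturbed trajectory, giving for the deviations
$\Delta\chi = \chi^* - \chi$ (unperturbed minus perturbed):

$$\Delta\tau_{ext} \;=\; \Delta\bar Y\,\bar\pi \;+\; D_q\,\Delta\dot q
  \;+\; K_q\,\Delta q .$$

Assumptions: deviations small enough for first-order expansion (the designed
perturbations evoke millimetre-scale deviations); $D_q$, $K_q$ constant over
the 115 ms window; $K_q$ symmetric positive definite (spring-like intrinsic
muscle field), enforced structurally by estimating its Cholesky factor;
$D_q$ left unconstrained (four free elements).

## 2. Feedback jerk isolation

Point-to-point reaches are close to minimum-jerk, so the jerk of the
unperturbed movement is concentrated at low frequencies, while the designed
perturbation (section 3) evokes feedback jerk well above them. Per Cartesian
axis the cutoff is the lowest frequency above which the averaged feedback
jerk energy spectral density exceeds the unperturbed one
($\psi_{FB} = \psi_P - \psi_{UP} > \psi_{UP}$), required to hold for three
consecutive bins to reject single-bin noise (`select_cutoffs()`,
`crossing_frequency()`). The high-pass filter is an order-10 Butterworth
realized as cascaded biquads (numerically essential at a cutoff three
decades below the sample rate) and applied forward-backward for exactly zero
phase lag.

Two implementation decisions deserve emphasis because both were found — by
twin-referenced validation on the simulator — to matter at the level of
doubling or halving estimation errors:

* **One measurement chain per derivative order.** All perturbed-trial
  derivatives come from the same seventh-order Savitzky-Golay operators
  (window sized so the smoother's $-3$ dB point is 50 Hz). The first
  integration of the high-passed jerk is evaluated in commuted form — the
  zero-phase high-pass applied to the SG acceleration — which is identical
  for LTI operations and keeps the variational acceleration on the same
  operator as the acceleration it is added to. Velocity and position follow
  by trapezoidal integration.
* **Initial conditions half a window before onset.** Twins are identical up
  to perturbation onset, so variational states vanish there — but only in
  the *raw* signal. The acausal SG window (±23 ms at 2 kHz) already straddles
  post-onset data at the onset sample, so the measured-chain variational
  quantities are *not* zero at onset. Anchoring the zero initial conditions
  at the onset sample injects a constant offset correlated with the
  perturbation direction into every trial; pooled across trials this biased
  stiffness estimates by roughly a factor of two. Anchoring them half an SG
  window before onset removes the bias. This deviates deliberately from the
  naive "zero at onset" convention.

Unperturbed forces follow from the admittance relation
$u^*_{ext} = -(M_{adm}\ddot x^* + D_{adm}\dot x^*)$ applied to the estimated
unperturbed kinematics; joint-space quantities via the inverse kinematics
(elbow-flexed branch) and the Jacobian-transpose map. The decomposition
identity $\chi^* = \Delta\chi + \chi$ holds exactly per channel by
construction.

**Twin-referenced quality metrics** compare against the twin's signals
passed through the *same* measurement chain (SG derivatives, admittance
force), because no estimator operating behind a 50 Hz conditioning chain can
recover content the chain removes; the metrics then score the isolation step
itself. Raw-state references remain available
(`twin_variational(processed = FALSE)`).

## 3. Perturbation design

The acceleration profile concatenates two sinusoidal blocks
$\xi(t)=\tfrac12 A_p(1-\cos(4\pi t/T_p))$ (sign-flipped on the second half
of each block): a deviating block of duration $T_{p,1}$ and a retracting
block of duration $T_{p,2} = \tfrac32 T_{p,1}$. Each block contributes zero
net velocity and a displacement $\propto A_p T_p^2$ (closed form
$A_pT_p^2/8$), so $A_{p,2} = A_{p,1}(T_{p,1}/T_{p,2})^2$ cancels the
displacement exactly; all profiles (analytic, not numerically integrated)
return to zero at $T_{pert}=T_{p,1}+T_{p,2}$ to machine precision. The force
profile is the admittance image $M_{adm}a + D_{adm}v$, normalized so its
first peak equals $A_{pert}$. Directions come from
$\Phi = \{(\pi/12)k\}_{k=1..24}$ minus the four cardinal multiples of
$\pi/2$ — 20 angles.

Defaults: dynamic task $A_{pert}=40$ N, $T_{p,1}=70$ ms
($T_{pert}=175$ ms); static task $T_{p,1}=160$ ms ($T_{pert}=400$ ms) with
the *position* profile rescaled to 8 mm (open-loop rendering).

## 4. The synthetic-data generator

`simulate_dynamic_trial()` integrates the coupled arm + admittance system
with fixed-step RK4 at $f_s = 2$ kHz (C++ core). Components:

* **Muscles.** Six lumped muscles with a constant $6\times2$ moment-arm
  matrix (shoulder pair ±40 mm, elbow pair ±25 mm, bi-articular pair
  ±28 mm/±28 mm). Tension $m = a + D_m\dot e + K_m e$ with
  $K_m = K_0 + K_1 a$ and $D_m = K_m/12$; $e$ is the muscle-level tracking
  error against the reference movement. The intrinsic joint impedance is the
  congruence $K_q = J_m^\top \mathrm{diag}(K_m) J_m$ (symmetric positive
  definite), $D_q = K_q/12$ — this is the ground truth the estimators are
  scored against, window-averaged.
* **Feedforward.** Inverse dynamics of the minimum-jerk reference (including
  the admittance load), distributed minimum-norm across muscles plus the
  minimal per-pair co-contraction keeping every activation at or above
  $a_0$. With noise off, tracking is exact by construction.
* **Reflex.** A single delayed PD loop on the muscle tracking errors with
  $\delta_s = \delta_v = 115$ ms. Because $T_{est} = \delta_s$, no feedback
  response to the perturbation can occur inside the estimation window — the
  window-internal variational torque is exactly the intrinsic impedance,
  which is what makes ground-truth scoring clean. In the static task the
  loop is kept on by default (`reflex_on`), contributing a sub-percent
  model violation there.
* **Noise.** Zero-mean Brownian motion per muscle channel (Gaussian
  increments of variance $dt$, mean-removed), fifth-order Butterworth
  low-pass at $f_{c,N} = 2$ Hz, scaled by $\alpha_N \cdot$ `base_scale`.
  $\alpha_N = 12.5$ is the dimensionless amplitude varied in validation
  studies; `base_scale` = 0.46 N was calibrated *once* so the default noise
  reproduces a published peak-speed standard deviation of ≈ 9 mm/s across
  repeated 2 s reaches, and is not revisited.
* **Twins.** Perturbed trials share their noise stream with an unperturbed
  twin; pre-onset series are bit-identical, and the perturbation onset is
  the twin's first crossing of $x_2 = 0.4$ m.

Calibration notes. The arm segment defaults give
$\bar\pi \approx (0.174, 0.058, 0.073)$ kg m² and the muscle defaults a
window-averaged intrinsic stiffness around
$[29, 14; 14, 17]$ N m/rad — the order of published simulated values for
this task; neither is an anthropometric authority. The co-contraction
baseline $a_0 = 20$ N is deliberately high enough that no muscle goes slack
under the largest designed perturbation: slack muscles activate the
defensive tension clamp, violate the linear tension model, and (as the
noise-free self-consistency oracle exposed) bias the static stage even
without noise.

What the generator does **not** emulate: Hill-type force-length-velocity
curves, tendon compliance, heteronymous reflex gains (so the true stiffness
has no antisymmetric part), sensor noise and quantization, trial-to-trial
reference variability (real subjects' reference movements differ; here only
activation noise varies them — one reason the synthetic movements are slower
than published human ones, peak speed 234 mm/s vs ≈ 378 mm/s for the same
nominal duration). A green test therefore establishes correctness of the
*method pipeline* under the stated world, not physiological fidelity.

## 5. Estimation stages

**Static stage** (`static_bip_estimate()`): all 100 trials pooled into one
linear least squares solve of the full 11-parameter model; damping and
stiffness act as nuisance parameters absorbing the evoked feedback so they
do not bias $\bar\pi$. In the open-loop static task the variational
kinematics are known a priori (the commanded 8 mm profile) — the exact limit
of jerk isolation when the unperturbed side has no jerk content — but the
unperturbed *force* is noise-driven and wanders at the noise bandwidth.
A constant pre-onset baseline cannot follow that wander (2–8% BIP errors);
instead the cutoff-crossing rule is applied to the *force* spectra
(`select_cutoffs(signal = "force")`) and the same zero-phase high-pass is
applied to **both** sides of the regression (state-variable filtering, which
preserves any LTI model exactly). This is the static-task counterpart of
feedback jerk isolation and brings the stage to ≈ 1% accuracy.

**Dynamic stage** (`dynamic_impedance_estimate()`): with $\bar\pi$ fixed,
$\bar b = \Delta\hat\tau_{ext} - \Delta\bar Y\hat{\bar\pi}$ and
$f(\bar\zeta) = D_q\Delta\hat{\dot q} + L_qL_q^\top\Delta\hat q - \bar b$
is minimized over seven parameters by Levenberg-Marquardt with analytic
Jacobian. Initialization is deterministic: the unconstrained linear solution
with its stiffness block symmetrized and eigenvalue-clipped to the positive
cone, Cholesky-factored. Tolerances: gradient norm $<10^{-10}(1+\mathrm{cost})$,
at most 200 iterations (non-convergence is an error carrying the final
gradient norm); solutions are normalized to a non-negative Cholesky diagonal
(the mirror ambiguity). The 60 trials are estimated on 41 sliding 20-trial
windows; `interval_sweep()` repeats the solve for shorter windows and flags
ill-conditioning.

Degenerate inputs: rank-deficient static regressions abort with the singular
values; windows shorter than ≈ 20 ms are flagged by condition number rather
than silently returned; full-extension arm configurations are representable
but the simulator never reaches them.

## 6. Reference estimators

For head-to-head comparisons on identical data: **GOM**-style estimation
subtracts each perturbed trial's state at onset, averages the unbiased
trajectories across perturbed trials (unperturbed trials unused) as the
reference, and solves the same joint-space model by unconstrained linear
least squares (stiffness symmetry not enforced). **ERD**-style estimation
takes onset offsets as the unperturbed state, differentiates variational
positions with the same SG operators (to isolate methodological rather than
filter differences), and fits diagonal Cartesian inertia/damping/stiffness
per axis. Both use $T_{est} = 115$ ms. Their documented failure modes
reproduce: the GOM reference degrades from accelerations down to positions
(movement variability), and ERD's constant-state assumption is invalid for
reaching, inflating its position errors by orders of magnitude.

## 7. Known limitations

* The selected cutoffs trade leakage of unperturbed content against loss of
  genuine low-frequency feedback content; the residual few-percent isolation
  error is the documented noise floor of the approach, not removable by the
  pipeline.
* Impedance is assumed constant within each window; slow modulation across
  the movement shows up as cross-window variation, not within-window fit.
* The static stage's state-variable filtering assumes constant D/K nuisance
  dynamics per trial; the delayed reflex inside the 400 ms window violates
  this mildly (sub-percent at default gains).
* Estimates inherit the conditioning of the perturbation design: directions
  near a Cartesian axis identify the orthogonal components weakly, which is
  why 20 angles are pooled.
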