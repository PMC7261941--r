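# armfji

Estimation of the **involuntary impedance components of the human arm** —
base inertial parameters, joint damping, and joint stiffness — from
force-perturbed planar movements, via **feedback jerk isolation**, together
with the neuromechanical arm simulator used to validate the method on
synthetic data with known ground truth.

## The problem

When a human arm is perturbed during movement, restoring torques arise from
three involuntary sources: rigid-body inertia, muscle-intrinsic
viscoelasticity, and short-latency reflexes. Voluntary (cognitive) reactions
join only after a delay δ_v ≈ 115 ms. Quantifying the involuntary components
matters for physical human-robot interaction: a robot controller that knows
the human's stiffness and damping can guarantee stable, comfortable
collaboration. The catch is that estimation must finish *within* the 115 ms
window (to exclude voluntary feedback) and needs the **unperturbed** states of
the movement that the perturbation destroyed.

## The method

For a two-link planar arm with joint angles `q = (q1, q2)`, gravity-free
rigid-body dynamics are linear in the three base inertial parameters (BIP)
`π̄ = (I1 + m2·l1², I2, m2·lc2·l1)` through the base regressor `Ȳ(q, q̇, q̈)`.
Linearizing the involuntary feedback about the unperturbed trajectory gives
the identification model

    Δτ_ext = ΔȲ·π̄ + D_q·Δq̇ + K_q·Δq ,

where `Δχ = χ* − χ` are deviations of the perturbed movement from its
unperturbed twin. The pipeline:

1. **Feedback jerk isolation.** Point-to-point reaches are minimum-jerk, so
   the unperturbed jerk `x⃛` lives at low frequencies; the perturbation is
   designed (two concatenated sinusoidal acceleration blocks, 175 ms total)
   so the evoked feedback jerk lives above them. Cutoffs are read off the
   averaged jerk energy spectral densities (`ψ_FB > ψ_UP`), and an order-10
   zero-phase Butterworth high-pass plus integration from onset reconstructs
   the variational kinematics, the admittance relation
   `u_ext = u_pert − M_adm·ẍ − D_adm·ẋ` the variational forces.
2. **Static stage.** 100 open-loop 8 mm position perturbations (5 postures ×
   20 angles) pooled into one linear least squares solve for the
   11-parameter model; the three BIP elements are kept.
3. **Dynamic stage.** 60 perturbed reaches (20 angles × 3 reps, 40 N, onset
   at the x2 = 0.4 m crossing), 41 sliding 20-trial windows, T_est = 115 ms.
   With `K_q = L_q·L_qᵀ` (Cholesky: symmetric, positive semidefinite by
   construction) the seven remaining parameters are found by
   Levenberg-Marquardt nonlinear least squares.

The simulator couples the two-link arm (six lumped muscles, tension
`m = a + D_m·ė + K_m·e`, `K_m = K_0 + K_1·a`, `D_m = K_m/12`, PD reflex
delayed by 115 ms, low-pass-filtered Brownian activation noise) to an
admittance-rendered manipulandum (`M_adm = diag(5,5)` kg,
`D_adm = diag(20,20)` N·s/m), integrated by fixed-step RK4 at 2 kHz in C++.
Every perturbed trial carries its noise-identical unperturbed twin, so
isolation quality and parameter recovery can be scored exactly. Reference
estimators in the style of the averaged-unbiased-dynamics method (GOM) and
the diagonal-Cartesian offset method (ERD) are included for head-to-head
comparison.

## Worked example

```r
library(armfji)

static  <- run_static_task(seed = 11)            # 100 open-loop trials
bip     <- analyze_static(static)
round(100 * bip$nae, 2)
#> [1] 0.79 1.25 0.31                              # BIP errors, percent

dynamic <- run_dynamic_task(seed = 12)           # 60 twin pairs, ~30 s
fit     <- analyze_dynamic(dynamic, bip$pi_hat)  # isolate + 41 windows
fit$iso$esd
#> ESD set: 60 unperturbed / 60 perturbed trials, cutoffs f_c_HP = [1.59, 1.89] Hz
print(fit$estimates[[1]])
#> Involuntary impedance estimate
#>   pi_hat = [0.1756, 0.0584, 0.0727] kg m^2
#>   D_q = [2.27 1.14; 1.14 1.39] N m s/rad
#>   K_q = [29.21 14.71; 14.71 17.25] N m/rad  (SPD: TRUE)
#>   residual = 24.67, 4 iterations
round(100 * colMeans(fit$nae_K), 2)              # stiffness errors, percent
#>   11   12   21   22
#> 2.28 1.47 1.47 3.56
```

The numbers mean: the static stage recovers the three base inertial
parameters to ~1%, the selected high-pass cutoffs sit just below 2 Hz
(above the movement band, below the feedback band), and the dynamic stage
recovers every stiffness element to within a few percent of the simulator's
true intrinsic impedance (which is ≈ [29, 14; 14, 17] N·m/rad at the
default co-contraction).

A command-line pipeline is installed under `inst/cli/armfji`
(`simulate`, `isolate`, `estimate`, `compare`, `validate`, `report`),
configured by JSON and fully seeded.

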