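# ikweights

Model-based quantification of inter-joint coordination in kinematically
redundant systems — human reaching, exoskeleton-assisted movement,
human–prosthesis chains. Instead of correlating joint angles, the
package explains recorded kinematics through the task they serve: joint
velocities are modeled with a **weighted pseudo-inverse of the
Jacobian**, and the diagonal weight matrix — the set of relative joint
costs that best reproduces the data — is **identified from the
recordings** by an iterative, box-constrained quadratic-programming
estimator.

## The model in brief

With joint velocities `q̇ ∈ ℝⁿ`, end-effector velocities `ẋ ∈ ℝᵐ`
(`n > m`) and Jacobian `J(q)`, each sample is modeled as

    q̇ₖ = J̄ₖ# ẋₖ + vₖ ,   Jₖ# = W⁻¹Jₖᵀ(JₖW⁻¹Jₖᵀ)⁻¹ ,   Jₖ vₖ = 0

where `W = diag(w₁…wₙ)`, `wᵢ ∈ (0, 1]`, `max wᵢ = 1`. `Jₖ# ẋ` is the
joint velocity minimizing `q̇ᵀWq̇` subject to producing the observed
end-effector motion, so `wᵢ` reads as the *cost* of joint *i*: costly
joints contribute little, cheap joints carry the task. The estimator
alternates (a) decomposing every sample under the current weights,
attributing a fraction `γ` (the *null-space projection ratio*) of the
projected velocity to self-motion, with mean residual
`(1−γ)‖N q̇ₖ‖` as the convergence criterion, and (b) re-solving for the
weights from the linearized relation `W(Q̇−V̄) = Ū` as a quadratic
program over the box `[ε, 1]ⁿ`, followed by max-normalization. For
reporting, weights transform to contribution coefficients
`βᵢ = wᵢ⁻¹ / Σₖ wₖ⁻¹` (they sum to 1).

## Worked example

Generate a synthetic benchmark whose ground-truth weights are known,
then recover them:

```r
library(ikweights)

d <- random_benchmark(n = 5, m = 3, K = 500,
                      w_star = c(1, 0.8, 0.6, 0.4, 0.2),
                      sigma = 0.2, seed = 42)
fit <- ik_fit(d, gamma = 0.6)
summary(fit)
#> Inverse-kinematics weight fit
#>   5 joints, 3 task dims, 500 samples; 54 updates
#>   weights: 1.0000 0.8073 0.6237 0.4133 0.2244
#>   contributions: 0.0933 0.1156 0.1496 0.2258 0.4158
#>   mean residual: 0.1073 (started at 0.1792); converged (stationary)
#>
#>        joint1 joint2 joint3 joint4 joint5
#> weight 1.0000 0.8073 0.6237 0.4133 0.2244
#> beta   0.0933 0.1156 0.1496 0.2258 0.4158
```

The recovered weights sit within ~0.02 of the generating
`[1, 0.8, 0.6, 0.4, 0.2]`; joint 5, the cheapest, carries the largest
contribution share (β ≈ 0.42). The residual falls from 0.179 (identity
weights — the conventional unweighted pseudo-inverse) to the noise
floor left by the injected null-space motion.

The decomposition itself, on the textbook two-prismatic-joint example:

```r
decompose_velocity(c(0, 1), matrix(c(1, 1), 1), weights = c(1, 1/9))
#> task: 0.1 0.9
#> null: -0.1  0.1
```

Cohort workflows (`estimate_cohort_weights()`, `cohort_contributions()`,
`nullspace_utilization()`, `paired_hotelling()`) fit weights per
participant and condition, aggregate contribution coefficients, compare
null-space profiles under estimated vs identity weights, and contrast
conditions with a paired Hotelling T² test. Recordings enter through a
plain-text interchange format (one directory per trial:
`joint_velocities.csv`, `endeffector_velocities.csv`, `jacobians.csv`,
`meta.json`); see `read_kin_data()` / `read_cohort()`.

A thin command-line front end covers the same ground:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ikweights.R", package="ikweights"))')" \
    estimate --input trial_dir --gamma 0.9 --out fit.json
```

with subcommands `estimate`, `benchmark`, `reproduce`, `contributions`,
`contrast` (exit codes: 0 success, 1 input error, 2 missing cohort
data, 3 non-convergence).

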