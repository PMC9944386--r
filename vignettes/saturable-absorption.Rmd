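---
title: "Saturable absorption models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturable absorption models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satabs)
```

## The model family and its assumptions

`satabs` models the amount of drug `A(t)` remaining at the absorption
site under carrier-mediated (saturable) transport. The generalized rate
law is

$$\frac{dA}{dt} = -K_{a,max}\,\frac{A^{\gamma_1}}{A^{\gamma_2} + A_{50}^{\gamma_2}},
\qquad A(0) = A_0 ,$$

a Hill-type law with the numerator and denominator exponents decoupled.
The assumptions are those of a single absorption compartment: one dose
deposited at `t = 0`, no further input, and no representation of
distribution or elimination — the curve describes what remains *to be
absorbed*, irrespective of administration route. The equation is
autonomous and its right-hand side is non-positive for all `A >= 0`, so
every trajectory is monotone non-increasing and stays in `[0, A0]`.

Setting `gamma1 = gamma2` recovers classical Hill kinetics;
`gamma1 = gamma2 = 1` is Michaelis–Menten; `gamma1 = 1, gamma2 = 0`
collapses the denominator to the constant 2, i.e. first-order absorption
with effective rate constant `k_a = K_a,max / 2`.

## Parameters

| parameter | meaning | units | default behaviour |
|-----------|---------|-------|-------------------|
| `k_a_max` | maximum absorption rate | amount^(1+γ2−γ1) / time | required, `> 0` |
| `a50`     | amount at half-maximal rate | amount | required, `> 0` |
| `gamma1`  | numerator exponent | — | finite real |
| `gamma2`  | denominator exponent | — | finite, `>= 0` |
| `a0`      | dose | amount | `>= 0`; `0` yields the zero profile |

No unit system is enforced; the documentation and the CLI help use hours
and mg as conventions. Note `k_a_max` only has units of amount/time when
`gamma1 - gamma2 = 1`; in general it absorbs the dimensional residue of
the exponents. `gamma2 < 0` is rejected at validation rather than routed
to the closed forms: the Lambert-W branch analysis and the physical
meaning of `a50` hold for the natural `gamma2 >= 0` regime, and a clear
error beats a silently wrong branch.

## Case dispatch

`classify_case()` assigns each bundle to exactly one of five regimes
(closed-form cases B, C, D, the explicit power-law branch at
`gamma2 = 0, gamma1 != 1`, and the general implicit case A). Dispatch
follows the denominators of the integrated relation: the degenerate
exponent of the general antiderivative is `gamma2 - gamma1 + 1`, so the
dedicated logarithmic branch applies at `gamma2 - gamma1 = -1` and the
general branch everywhere else. Exponent equality on floating-point
input is tested within a band `tol = 1e-12` (relative to 1): exponents
are user-chosen constants of order one, so anything within 1e-12 of a
special value is treated as that value; callers may widen the band.

## Closed forms through the Wright omega function

Cases B and D invert their integrated relations through the principal
Lambert-W branch. Both inversions were re-derived from the integrated
relations and verified by back-substitution and by the ODE oracle; they
are evaluated via the Wright omega function `omega(z)`, the solution of
`omega + log(omega) = z`:

* **Case B** (`gamma1 = 1, gamma2 > 0`): with `u = (A/A50)^gamma2`,
  `A(t) = A50 * omega(z_B)^(1/gamma2)` where
  `z_B = (A0/A50)^gamma2 + gamma2*log(A0/A50) - gamma2*K_a,max*t/A50^gamma2`.
* **Case D** (`gamma1 != 1, gamma2 = gamma1 - 1 > 0`): with
  `v = (A50/A)^gamma2`, `A(t) = A50 / omega(z_D)^(1/gamma2)` where
  `z_D = (A50/A0)^gamma2 + gamma2*log(A50/A0) + gamma2*K_a,max*t`.

Working with `omega` rather than `W0(e^z)` keeps the argument in log
space: `z` can reach 1e4 for small `a50` or large doses, where `e^z`
would overflow long before the solution itself misbehaves. `omega` is
computed by Newton iteration on `f(w) = w + log(w) - z` (monotone,
smooth for `w > 0`), started from `e^z` for `z < -1`, `z - log z` for
`z > 2`, and a linear blend between; iteration stops at relative steps
below `4 * eps`. `lambert_w0(x)` is `omega(log x)` with `W0(0) = 0`.
Only the principal branch is needed: every W argument arising from
positive amounts is non-negative.

At `gamma2 -> 0` case B degenerates continuously into case C (the
denominator of the rate law tends to 2); the test suite checks agreement
at `gamma2 = 1e-8` to 1e-6 relative.

## The implicit solver

For the general regime the integrated relation `lhs(A) = lhs(A0) -
K_a,max * t` has no elementary inverse, but `lhs` is strictly increasing
(its derivative is the integrand `(A^γ2 + A50^γ2)/A^γ1 > 0`), so the
root in `(0, A0]` is unique. `solve_amount_implicit()`:

1. tests analytically (from the exponent signs, never numerically)
   whether `lhs` has a finite limit at `0+` — true iff `gamma1 < 1`
   given `gamma2 >= 0` — and returns exactly 0 with `hit_zero` set when
   `t` reaches the finite end time `t_end = lhs(A0)/K_a,max`;
2. brackets the root by geometric descent from `A0/2` (backing off by a
   geometric mean if a trial point overflows the negative-power terms);
3. refines with Brent's method (`stats::uniroot`, bisection safeguarded
   by superlinear interpolation; defaults `tol_rel = 1e-12`,
   `tol_abs = 1e-15 * A0`, 200 iterations);
4. polishes with up to three Newton steps using the analytic derivative,
   reaching machine precision — the test suite holds the implicit route
   to 1e-9 relative agreement against every closed form.

Because the ODE is autonomous, solving to `t1 + t2` must equal solving
to `t1` and restarting from the reached amount; this semigroup property
is exercised in the tests. For `gamma1 <= 0` the rate does not vanish at
`A = 0`; the solver clamps at 0 and flags `hit_zero`, a pragmatic choice
for a regime with no established physical reading.

## The ODE oracle

`integrate_modified()` wraps `deSolve::lsodar` with `rtol = 1e-10`,
`atol = 1e-12 * A0` and a root function that terminates integration when
the state reaches the `atol` floor (for `gamma1 < 1` the right-hand side
has unbounded derivative at zero, so running through the zero crossing
would thrash the step controller); later grid times are clamped to 0.
The oracle exists to be *independent* of the closed forms — it evaluates
only the rate law — and the acceptance checks hold every closed form to
1e-6 relative agreement against it over a 34-bundle grid
(`gamma2` in {0.25, 0.5, 1, 2, 4} for case B, `(gamma1, gamma2)` in
{(1.5, 0.5), (2, 1), (3, 2)} for case D, `a50/a0` in {0.1, 0.5, 2, 10},
plus case C and power-law bundles, 50 time points on [0, 24] h).

Two tolerance caveats, deliberate and verified: the adaptive
integrator's *global* error over a 36 h horizon runs one to two orders
above its per-step `rtol` (measured about 5e-10 at `rtol = 1e-12`
against the exact exponential), so unit tests bound ODE-vs-analytic
agreement at 1e-9, and the self-convergence check compares `rtol = 1e-8`
against `1e-10` with a 1e-6 band. The closed forms and implicit solver
are *not* subject to these caveats; they are exact up to root-finder
tolerance.

For the power-law bundle with `gamma1 < 1` the trajectory is identically
zero beyond its finite end time; relative error against the oracle is
compared on `t <= 0.99 * t_end` (relative error is undefined at 0), and
the zero tail is checked separately: the closed form vanishes exactly at
`t_end` and the oracle's crossing below `1e-6 * A0` lands within 0.1% of
it.

## Synthetic observations and fitting

`simulate_observations()` emulates a single-subject amount–time assay:
the exact model curve plus independent Gaussian measurement error,
either additive (constant SD) or proportional (SD = scale × amount),
with negative draws resampled (bounded retries, then clamped) so amounts
stay physical. One explicit seed governs all noise and the caller's RNG
stream is restored afterwards. What it does **not** emulate: sampling
from concentration data through a disposition model, between-subject
variability, model misspecification, censoring below a quantification
limit, or correlated errors. Passing recovery tests therefore shows the
estimator works when the model is true and the error is as declared — a
prerequisite, not a demonstration of robustness on clinical data.

`fit_params()` minimizes squared residuals with Levenberg–Marquardt
(`minpack.lm::nls.lm`), evaluating the model through the closed forms
(or the implicit solver in case A) — the point of having exact solutions
is precisely that each optimizer proposal costs microseconds rather than
an ODE solve. Choices made where the field offers no single convention:

* **Loss.** OLS on amounts (suited to additive error) and least squares
  on log amounts (suited to proportional error) are both offered; no
  error model is canonical for absorption data, so the choice is the
  user's. Recovery tests pair each noise model with its matched loss.
* **Scale.** Free parameters are optimized as logarithms, enforcing
  positivity without constrained optimization.
* **Identifiability.** The dose `a0` is treated as known (it is, in a
  dosing experiment). Degenerate designs — fewer observations than free
  parameters plus one, a single time point, constant amounts — raise
  errors rather than returning a silently flat fit. Freeing the
  exponents jointly with `k_a_max`/`a50` is allowed but weakly
  identified on sparse designs.
* **Start values.** `k_a_max` from a secant slope over the two earliest
  observations, `a50` at the mid-range of observed amounts, exponents
  at 1; user-supplied starts override.
* **Uncertainty.** A curvature-based proxy (residual variance times the
  inverse Hessian of the log-scale problem, delta-method mapped back) is
  reported as `covariance_proxy`; it is a local quadratic approximation,
  not a profile or bootstrap interval.

The recovery study run by the acceptance tests uses 100 seeded
replicates of 20 (then 80) log-spaced observations on [0.1, 24] h at 2%
proportional noise — sizes chosen as a realistic single-subject rich
design, with the 80-point arm demonstrating that errors shrink as the
design grows.

## Reference scenarios

`cmd_fig1()` writes five curves (dose 150 mg, reference rate
`k_a = 1/3` per hour, 0–36 h): first order; Michaelis–Menten with
`a50 = 10 a0` and `k_a_max = a50 * k_a`; the `gamma1 = 1` family at
`gamma2 = 0.98` and `1.02` with `a50 = a0/2`; and case D
(`gamma1 = 2, gamma2 = 1, k_a_max = k_a`). They illustrate two
structural facts the tests verify quantitatively:

* **Saturation vanishes when `a50 >> a0`.** With `k_a_max = a50 * k_a`
  the effective rate constant `k_a_max/(A + a50)` is within 10% of
  `k_a` everywhere on the curve, and the Michaelis–Menten profile
  tracks the first-order one within 10% over the full window. The 10%
  statement uses the symmetric relative difference
  `|a - b| / max(a, b)`: at these exact parameters the late-time gap is
  9.5% symmetric but crosses 10% when normalized by the (smaller)
  first-order amount alone, so the convention matters and is fixed here
  once.
* **Small exponent deviations matter.** At `a50 = a0/2` the
  `gamma2 = 0.98` and `1.02` curves bracket the `gamma2 = 1` member of
  the same family pointwise, with visibly different profiles despite
  2% exponent changes.

The time window (0–36 h, not stated with the original scenario set) is
chosen so first-order absorption is >99.99% complete; the grid density
(0.25 h) is cosmetic. The reproduction is structural — curve shapes,
orderings, limits — not pixel-level.

## Known limitations

* `gamma2 < 0` bundles are rejected; no closed form is attempted.
* Single compartment, single bolus input: no elimination, no
  distribution, no dosing schedules, no time-varying coefficients.
* Amount data only; fitting concentration data requires a disposition
  model, out of scope.
* The power-law branch with `gamma1 > 1` decays algebraically and never
  reaches zero; end-time queries return `Inf` there, which is the
  mathematically correct but occasionally surprising answer.
* CSV numeric output carries 12 significant digits; consumers wanting
  bit-exact round trips should use the in-memory API.
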