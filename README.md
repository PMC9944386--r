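# satabs — saturable drug-absorption models, solved exactly

Pharmacokinetic absorption is usually modelled as first order: the amount
`A(t)` remaining at the absorption site decays as `dA/dt = -Ka * A`. For
many drugs (ascorbic acid, metformin, cefuroxime axetil, several
monoclonal antibodies, paliperidone palmitate) the transporters mediating
uptake saturate at high drug amounts, and the constant rate must be
replaced by a Hill-type law. `satabs` implements that family of saturable
absorption models for anyone who simulates or fits amount–time data:
PK modellers, simulation scientists, and method developers who need fast,
exact trajectories instead of repeated numerical integration.

## The models

The generalized saturable model decouples the two Hill exponents:

    dA/dt = -Ka,max * A^g1 / (A^g2 + A50^g2),      A(0) = A0

where `Ka,max` is the maximum absorption rate, `A50` the amount at which
the rate is half-maximal, and `g1`, `g2` shape exponents. Special members:

| exponents            | model                          | solution              |
|----------------------|--------------------------------|-----------------------|
| `g1 = g2 = g`        | Hill kinetics                  | implicit (root-found) |
| `g1 = g2 = 1`        | Michaelis–Menten               | Lambert W closed form |
| `g1 = 1, g2 > 0`     | saturable ("case B")           | Lambert W closed form |
| `g1 = 1, g2 = 0`     | first order with `Ka,max/2`    | exponential           |
| `g2 = g1 - 1 > 0`    | "case D"                       | Lambert W closed form |
| `g1 != 1, g2 = 0`    | power law                      | explicit; finite end time if `g1 < 1` |
| anything else        | general ("case A")             | implicit (root-found) |

The Lambert-W cases are evaluated through the Wright omega function
(`omega + log(omega) = z`), keeping every argument in log space so no
`exp` overflow can occur. The general case is solved by monotone
bracketed root-finding (the integrated left-hand side is strictly
increasing, so the root is unique and convergence guaranteed), polished
by Newton steps with the analytic derivative. An independent adaptive
ODE integrator (`deSolve`) verifies every closed form, and
Levenberg–Marquardt least squares (`minpack.lm`) fits `Ka,max`, `A50`
(optionally the exponents) to observed amount–time data.

Amounts that vanish in finite time — a property of `g1 < 1` regimes,
matching the observation that oral absorption completes in finite
time — are detected analytically (`absorption_end_time()`).

## Worked example

```r
library(satabs)

p <- absorption_params(k_a_max = 25, a50 = 75, gamma1 = 1, gamma2 = 1,
                       a0 = 150)
p
#> Generalized saturable absorption parameters
#>   k_a_max = 25, a50 = 75, gamma1 = 1, gamma2 = 1, a0 = 150
#>   analytic case: CASE_B_LAMBERT

round(amount_closed_form(p, c(0, 1, 6, 24)), 4)
#> [1] 150.0000 133.6537  63.9454   0.3700
```

The dose (150 mg) is absorbed non-exponentially: the early decline is
nearly linear (the transporter runs at close to `Ka,max` while
`A >> A50`), then turns exponential as the amount falls below `A50` —
after 24 h only 0.37 mg remains. Fitting recovers the parameters from
noisy observations:

```r
obs <- simulate_observations(p,
         times = exp(seq(log(0.1), log(24), length.out = 20)),
         noise_model = "proportional", noise_scale = 0.02, seed = 7)
fit_params(obs, free = c("k_a_max", "a50"),
           fixed = list(gamma1 = 1, gamma2 = 1, a0 = 150), loss = "log")
#> Absorption model fit (log loss)
#>   k_a_max = 24.8061, a50 = 74.3167, gamma1 = 1, gamma2 = 1, a0 = 150
#>   free: k_a_max, a50; residual norm = 175.692; converged: TRUE (13 iterations)
#>   approx. s.e.: k_a_max = 0.476, a50 = 2.07
```

Both estimates land within 1% of the truth (25, 75). And absorption end
times are exact where they exist:

```r
absorption_end_time(absorption_params(1, 1, 0.5, 0, 100))
#> [1] 40
```

## Command line

A thin dispatcher over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "satabs.R", package = "satabs"))')
Rscript $CLI simulate --model modified --kamax 25 --a50 75 \
    --gamma1 1 --gamma2 1 --a0 150 --t-stop 24 --out profile.csv
Rscript $CLI fig1 --out-dir figures/         # reference scenario curves
Rscript $CLI compare --model modified --kamax 25 --a50 75 --gamma1 1 \
    --gamma2 1 --a0 150                      # closed form vs ODE, exit != 0 on mismatch
Rscript $CLI fit --data obs.csv --a0 150 --out fit.json
```

Subcommands: `simulate`, `fig1`, `compare`, `fit`, `make-synthetic`.
Logs go to standard error, data to files. CSVs carry 12 significant
digits so round-trips are lossless at double precision.

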