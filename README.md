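# bmecs

Bayesian/Maximum-Entropy (BME) reweighting of conformational ensembles
against ensemble-averaged NMR chemical shifts, with cross-validated selection
of the confidence hyperparameter θ.

## The problem

Intrinsically disordered proteins (IDPs) are described by conformational
ensembles, typically sampled by molecular simulation. Simulated ensembles are
systematically imperfect (force field, sampling, conditions), while NMR
chemical shifts (CS) report conformational averages with good sensitivity to
local secondary structure. BME reweighting perturbs the simulated ensemble's
frame weights *minimally* so that the weighted average of calculated shifts
matches the measured ones, balancing two terms:

```
L(w) = (m/2) * chi2_red(w)  -  theta * S_REL(w)

chi2_red = (1/m) * sum_i ( sum_j w_j CS_ji  -  CS_i^exp )^2 / sigma_i^2
S_REL    = - sum_j w_j log(w_j / w_j^0)        (<= 0;  N_eff = exp(S_REL))
```

The optimal weights are exponential tilts of the prior,
`w_j ∝ w_j^0 exp(-sum_i lambda_i CS_ji)`, with one Lagrange parameter per
observable; the package solves the smooth convex dual of `L` by damped
Newton iteration.

θ sets the confidence in the simulation relative to the data; it is hard to
choose because forward-model and force-field errors are unknown. The package
implements an interleaved cross-validation scan: odd frames train, even
frames validate, the training λ are transferred to the validation half, and
θ* is where the validation χ²_red is smallest. Weighted Wasserstein-1
distances between the train/validation (and, on benchmarks, ground-truth)
CS distributions confirm the overfitting onset, as do the λ root-mean-square
and a Wald–Wolfowitz runs test on residuals.

Because real reference ensembles are rarely available, the package ships a
seeded helix–coil benchmark generator: a "target" ensemble whose predicted
average shifts play the role of experiment, a mismatched prior ensemble, and
two parametric CS predictors differing by systematic (atom- and
conformation-dependent) plus random error. Secondary chemical shifts
(shift minus a random-coil reference computed from each ensemble's own coil
frames) are provided to demonstrate the cancellation of constant predictor
baselines.

## Worked example

Generate the default benchmark (4000 frames, 71 residues, helix propensity
0.6 over residues 25–45 in the target vs 0.25 in the prior, predictor error
on), scan θ, and refit at θ*:

```r
library(bmecs)
case  <- make_benchmark_case(generator_config())
calc  <- align_by_tags(case$prior_cs, case$targets)
truth <- align_by_tags(case$target_cs, case$targets)

scan <- theta_scan(calc, case$targets, target_matrix = truth)
sel  <- select_theta(scan)
print(sel)
#> <theta_selection> theta*=0.853168 (rule min_chi2_v)
#>   min_chi2_v: theta=0.853168 (chi2_v=0.0101242); d_tv_elbow: theta=0.385662

fit <- refit_full_ensemble(calc, case$targets, sel)
print(fit)
#> <reweight_solution> theta=0.8532 chi2_red=0.00559795 N_eff=0.1450 S_REL=-1.931 converged=TRUE (7 iter)

N <- nrow(case$prior_ss$codes)
h <- cbind(prior      = helical_fraction(case$prior_ss, uniform_weights(N)),
           reweighted = helical_fraction(case$prior_ss, fit$weights),
           target     = helical_fraction(case$target_ss, uniform_weights(N)))
round(colMeans(h[25:45, ]), 3)
#>      prior reweighted     target
#>      0.036      0.239      0.369
```

Reading the numbers: the validation χ²_red has an interior minimum at
θ* ≈ 0.85 — less reweighting underfits, more overfits the training half.
Refitting all frames at θ* keeps an effective sample size of 14.5% and moves
the mean helicity of the mismatched region from 0.04 most of the way to the
target's 0.37; it cannot get all the way because the prior ensemble contains
few long-helix frames and the predictor carries systematic error.

## Command line

```sh
Rscript inst/cli/bme.R generate --config config.json --out case/
Rscript inst/cli/bme.R scan --calc case/prior_cs.tsv --targets case/targets.tsv \
    --target-calc case/target_cs.tsv --theta-grid 100,0.001,30 --out scan/
Rscript inst/cli/bme.R fit  --calc case/prior_cs.tsv --targets case/targets.tsv \
    --theta 0.85 --out fit/
Rscript inst/cli/bme.R analyze --case case/ --weights fit/weights.tsv --out report/
```

(after installation, the wrapper is at
`system.file("cli/bme.R", package = "bmecs")`). Every command writes a
`manifest.json` with input digests, seed and version; seeded commands are
bit-reproducible. `--secondary-cs` (with `--calc-ss`, `--target-calc`,
`--target-ss`) switches scan/fit to secondary chemical shifts.

## Documentation

The methods vignette (`vignettes/bme-theta-selection.Rmd`) describes the
model, the θ-selection procedure, every generator default and what the
synthetic world does and does not emulate.
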