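---
title: "Ensemble reweighting with chemical shifts: model, theta selection, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble reweighting with chemical shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmecs)
```

## The model

A conformational ensemble of N frames with prior weights $w^0$ (uniform by
default) produces calculated observables $x_{ji}$ (frame $j$, observable
$i$; here chemical shifts in ppm). Experiments report the ensemble average
$\langle x_i \rangle$ with uncertainty $\sigma_i$, dominated in practice by
the forward-model (predictor) error rather than the measurement itself.
Reweighting finds new weights $w$ minimising

$$\mathcal{L}(w) = \frac{m}{2}\,\chi^2_{red}(w) \;-\; \theta\, S_{REL}(w),$$

with $\chi^2_{red} = \frac1m \sum_i (\sum_j w_j x_{ji} - x_i^{exp})^2 /
\sigma_i^2$ and $S_{REL} = -\sum_j w_j \log(w_j/w_j^0) \le 0$. The entropy
term penalises departure from the prior ensemble; $N_{eff} =
\exp(S_{REL})$ is the fraction of the ensemble that effectively survives.
$\theta > 0$ expresses confidence in the simulation relative to the data.
$\theta = 0$ (error-free maximum entropy) is outside this model and is
rejected; use a small positive value instead.

### Dual formulation and solver

The optimum is an exponential tilt $w_j \propto w^0_j
\exp(-\sum_i \lambda_i x_{ji})$ with one Lagrange parameter per observable
— N weights are controlled by only m parameters, which is itself a guard
against overfitting. The $\lambda$ minimise the convex dual

$$\Gamma(\lambda) = \log Z(\lambda) + \sum_i \lambda_i x_i^{exp}
  + \frac{\theta}{2} \sum_i \sigma_i^2 \lambda_i^2 .$$

This dual is not usually written out; it was derived here from the primal
by standard Lagrangian duality and is **verified against a brute-force
primal oracle** (exhaustive simplex grid at N = 3 and softmax-parameterised
direct minimisation up to N = 20) in the test suite — that equivalence test
is the keystone of the solver module.

Numerical choices:

* **Target-centred columns.** $\Gamma$ is evaluated with $x_{ji} -
  x_i^{exp}$ in place of $x_{ji}$, which changes nothing analytically
  ($\log Z$ absorbs the shift exactly) but removes an
  $O(|x|\,|\lambda|)$ cancellation: raw carbonyl shifts sit near 176 ppm
  while the informative differences are $\ll 1$ ppm.
* **Damped Newton.** Gradient $x^{exp}_i - \langle x_i\rangle_w + \theta
  \sigma_i^2 \lambda_i$ and Hessian $\mathrm{Cov}_w(x) + \theta\,
  \mathrm{diag}(\sigma^2)$ are analytic; the Hessian is positive definite
  for any $\theta > 0$, so Newton steps with Armijo backtracking converge
  quadratically. When the predicted decrease falls below the numerical
  noise floor of the log-sum-exp ($\sim 10^{-13}(1+|\Gamma|)$) the full
  step is taken without a line search — at that point the quadratic model
  is exact to machine precision and backtracking only stalls on rounding
  noise.
* **Convergence** is the sup-norm of the dual gradient $\le 10^{-8}$ ppm
  (default `grad_tol`), which enforces the stationarity identity
  $\langle x_i\rangle_w - x_i^{exp} = \theta \sigma_i^2 \lambda_i$ at the
  same scale. Non-convergence is flagged in the result, never raised:
  partial scans must stay visible.
* **Warm starts.** Scans run in descending $\theta$ and start each fit from
  the previous $\lambda$, which stabilises the strongly tilted small-
  $\theta$ fits.

## Selecting theta by interleaved validation

The procedure: split frames into odd (training) and even (validation)
halves; fit the training half across a $\theta$ grid; transfer each
$\lambda$ to the validation half *without refitting*; track
$\chi^2_{red}(t)$, $\chi^2_{red}(v)$, $N_{eff}(t)$, the RMS of $\lambda$,
and the mean per-observable Wasserstein-1 distance $D(t,v)$ between the
reweighted halves. With a synthetic ground-truth ensemble, $D(t,g)$ and
$D(v,g)$ are also available. $\chi^2(t)$ decreases monotonically with
$\theta$; $\chi^2(v)$ reaches an interior minimum and then grows as the
training half's sampling noise is being fitted — the operational
overfitting signal. Near the same point $D(t,v)$ develops high curvature
and starts growing.

Decisions taken where the procedure is underdetermined:

* **Split**: 1-based odd frames train, even validate; deterministic, no
  RNG. Equal halves keep the standard errors of the two means comparable.
  The split premise is that neighbouring frames are essentially
  uncorrelated; `lag1_autocorrelation()` is provided as a diagnostic, and
  the generator has a Markov-persistence knob to stress the correlated
  case. No k-fold or block variants are offered.
* **Selection rule**: the default `min_chi2_v` returns the *largest* grid
  $\theta$ attaining the minimal validation $\chi^2$ (ties prefer least
  reweighting). The advisory `d_tv_elbow` rule returns the $\theta$ of
  maximum discrete second difference of $D(t,v)$ against $\ln\theta$; "high
  curvature" has no formal definition in the source procedure, and the
  second difference is one defensible choice, so the rule is advisory
  only and both are reported in the diagnostics string.
* **Grid**: 30 log-spaced points from $10^2$ down to $10^{-3}$, wide enough
  to bracket both the no-reweighting plateau and the deep-overfitting
  regime on the benchmark.
* **Distances** always compare the *reweighted* training and validation
  halves under the current $\lambda$ (the ground-truth ensemble keeps its
  own fixed, uniform weights). After selection, the production weights
  come from refitting **all** frames at $\theta^*$: minimal perturbation
  is guaranteed only for the set the fit was run on, so the split fit is
  used solely to choose $\theta$.
* **Runs test**: residuals are ordered residue-major, atom (CA, CB, C)
  minor, so same-sign stretches are sequence-contiguous. Under BME the
  residual *signs* barely change as $\theta$ decreases (each average
  approaches its target from one side), which limits the test's value as
  a stopping rule — it is reported as a diagnostic, not used for
  selection.

## Secondary chemical shifts

The random-coil reference for each observable is the prior-weighted mean of
its shifts over the frames where that residue is in coil; the secondary
shift subtracts this reference per frame. Design choices:

* **Per residue position, not pooled by residue type** (default). The
  synthetic model has no residue-type chemistry, and on a single sequence
  the per-position average is what "the averaged shift of coil
  conformations" computes. A pooled per-atom-kind variant exists behind
  `pool = "atom_kind"`. This choice is deliberately prominent: with real
  data and tabulated coil scales the two differ.
* **Prior weights only.** References are fixed before any fitting so the
  observable map does not move across the $\theta$ scan.
* **Fallbacks.** A residue never seen in coil falls back to the atom
  kind's pooled coil mean with `coverage = 0` recorded; an atom kind with
  no coil frames anywhere is an error.
* Benchmark targets are transformed with the **target ensemble's own**
  coil reference, mirroring the treatment of the fitted ensemble.

The point of the construction: a predictor baseline error that is constant
per atom kind shifts an ensemble's shifts and its own coil reference by the
same amount, so secondary shifts cancel it exactly. The acceptance suite
shows the cancellation turning a strong spurious reweighting
($N_{eff} \approx 0.02$ at small $\theta$) into essentially none
($N_{eff} \ge 0.97$ across the whole grid).

## The synthetic world

The generator emulates the structure of a reweighting study on a disordered
helix-forming protein, not its chemistry. Defaults (all overridable;
chosen once as a realistic desk-scale world, not tuned to any test):

| parameter | default | why |
|---|---|---|
| `n_residues` | 71 | length of the ACTR benchmark system |
| `n_frames` | 4000 | desk-scale stand-in for ~30k-frame trajectories |
| `propensity_target` | 0.6 over residues 25–45, 0.1 elsewhere | one partially formed helix on a coil background |
| `propensity_prior` | 0.25 over the same region | an under-helical force field |
| `min_helix_run` | 3 | isolated one–two-residue "helices" are not helices |
| `coil_base` (CA, CB, C) | 56, 30, 176 ppm | typical random-coil values |
| `helix_delta` (CA, CB, C) | +2.6, −0.5, +1.8 ppm | standard helix secondary-shift convention |
| `neighbor_window` | 1 | shifts feel neighbouring residues, so long helices are more visible than short ones |
| `thermal_sd` | 0.3 ppm | per-frame predictor scatter |
| `predB_systematic` | 0.4 ppm on H-state, signed along `helix_delta` | systematic predictor disagreement that reads as extra helicity |
| `predB_random_sd` | 0.3 ppm | independent predictor-B noise |
| `target_sigmas` (CA, CB, C) | 1.06, 1.23, 1.32 ppm | published validation errors of a CS predictor |
| `cb_exclude` | residues 8, 15, 29, 40, 55 | glycine stand-ins; with the dropped termini the roster is 69 CA + 64 CB + 69 C = 202 observables |

On the sign convention: the source analysis reports predictor deviations
"negative C and CA and positive CB" as corresponding to higher helical
content, which conflicts with the standard helix secondary-shift signs
(positive CA/C, negative CB). The generator uses the standard convention;
the discrepancy is documented here rather than resolved. The predictor-B
default is *oriented* so that its systematic error mimics extra helicity,
reproducing the qualitative self-fit finding (reweighting lowers helicity)
under either convention.

Reproducibility: conformations, thermal noise and predictor-B noise draw
from separate streams derived from the base seed by fixed offsets
(+101/+202 conformations, +303/+404 thermal, +505 predictor-B), so
toggling one error source leaves the others bit-identical. When the prior
and target propensity profiles are identical the case is a *self-fit*: the
same conformations and the same thermal stream are reused, so predictor B
differs from the target predictions by exactly its systematic offsets plus
its own noise.

What the world does **not** emulate: residue-type-specific chemistry,
3-D coordinates, real DSSP assignment (simplified H/E/C codes are consumed
directly; only α-helix maps to H), trajectory autocorrelation (frames are
i.i.d. unless `markov_persistence > 0`), and the actual Sparta+/PPM error
structure (no quantitative offset table exists to copy). A green benchmark
test therefore establishes that the *method* behaves as described on a
controlled world — interior validation minimum, helicity recovery,
predictor-bias direction, secondary-shift cancellation — not that any
particular real force field or predictor would yield the same numbers.

The `rg_proxy()` observable (baseline minus a multiple of frame helicity
plus noise) exists only to illustrate why observables weakly coupled to
the fitted data make poor cross-validation signals.

## Degenerate inputs and edge policies

* Missing observable values are unsupported; files must be complete.
* A target value outside a column's value range makes that observable
  unreachable; the generator checks and reports this precondition
  (`target_in_support`), and the solver will simply report large residuals.
* One-frame observable matrices parse (the container allows N = 1) but
  cannot be reweighted (the solver requires N ≥ 2, the scan N ≥ 4).
* All-zero residuals are rejected by the runs test; single-signed
  residuals yield a well-defined (small-p) result.
* Weights round-trip through TSV at 17 significant digits, preserving
  normalisation to 1e-12.

## Known limitations

Gaussian errors only (no inequality restraints, no non-Gaussian noise);
entropy-based $N_{eff}$ only (the Kish size is deliberately not the
reported statistic); no NMR-STAR or predictor-native parsers; no plotting.
The scan cost is dominated by the per-theta Wasserstein distances
(O(m · N log N) each), not the Newton fits.
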