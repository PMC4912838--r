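---
title: "Optimal spike-based integration and nonlinear dendrites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal spike-based integration and nonlinear dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optidend)
```

## The problem

A cortical neuron is assumed to compute a function of the *analog* activities
(subthreshold membrane potentials) of its presynaptic partners, but it only
observes their *spikes*. The best it can do, in the mean-squared-error sense,
is to output the posterior expectation of the computed function given the
observed spike history. `optidend` implements the three ingredients needed to
study this idea quantitatively:

1. a generative model of presynaptic population activity with realistic
   correlation structure,
2. the Bayes-optimal postsynaptic response to spike trains from that model
   (an assumed-density filter, validated against a particle filter), and
3. simplified dendrite-like integrators that can be fitted to approximate the
   optimal response, plus the machinery to benchmark them and to fit the
   optimal response to uncaging-style stimulation experiments.

## The generative model

Each cell assembly carries a binary global state $z$ switching between
quiescent ($-$) and active ($+$) with rates $\Omega_+$ and $\Omega_-$ (Hz).
Given the state, the $N$ membrane potentials follow a multivariate
Ornstein–Uhlenbeck process with time constant $\tau$ (ms), resting level
$\pm\bar u$ (mV, relative to the spiking threshold) and process noise
$Q = 2\bar\Sigma/\tau$, so the stationary within-state covariance is
$\bar\Sigma$. Spiking is an inhomogeneous Poisson process with the
log-linear rate $g\,e^{\beta u}$, an absolute refractory period
$\tau_{refr}$ acting on spike *generation*, and transmission (release)
probability $p_{rel}$ applied afterwards; a suppressed spike still starts the
generator's refractory period, because release failure is invisible to the
spike generator.

The named presets (`load_preset()`) encode the two *in-vivo*-derived
statistics — `NC` (neocortical quiet wakefulness: up/down switching,
$\Omega_\pm$ = 4/10 Hz, $\bar u = 10$ mV, $\bar\Sigma_{ii}/\bar\Sigma_{ij}$ =
10/5 mV², $g = 1$ Hz, $\beta = 0.1$ /mV, $p_{rel} = 0.5$) and `HP`
(hippocampal sharp waves: $\Omega_\pm$ = 0.027/10 Hz, $\bar u = 2.3$ mV,
$g = 2$ Hz, $\beta = 0.6$ /mV, $p_{rel} = 0.2$) — plus the two control
statistics `ind` (independent neurons) and `cor2` (equicorrelated Gaussian
fluctuations, correlation $\rho$ free, $\rho \ge -1/(N-1)$), and per-figure
demonstration scenarios. Closed forms used throughout: stationary occupancy
$\Omega_+/(\Omega_+{+}\Omega_-)$, mean dwell times $1/\Omega_\mp$, and the
state-conditioned expected rate
$\gamma = g\exp(\beta\mu + \tfrac12\beta^2\Sigma_{ii})$.

Two conventions worth noting:

* **Time base.** Everything internal runs in milliseconds on half-open bins
  $[t, t+dt)$; rates are converted from Hz at the boundary. The default
  simulation step is $dt = 0.1$ ms; a warning fires if the per-bin spike
  probability exceeds 0.1.
* **State-conditioned means in simulation.** Conditioning on the *tracked*
  state underestimates the depolarisation gap $2\bar u$, because after each
  switch the potential relaxes with $\tau = 20$ ms while typical epochs last
  only 100–250 ms (for `NC` the tracked-state gap is ≈ 15.6 mV rather than
  20 mV). The acceptance machinery therefore measures the gap with the state
  *clamped*, which estimates $2\bar u$ unbiasedly.

## The assumed-density filter and the optimal response

The posterior over $(z, u)$ is approximated by a Bernoulli state probability
$\zeta$ times state-conditioned Gaussians $(\mu^\pm, \Sigma^\pm)$. Between
spikes the moments drift (decay to the prior, covariance relaxation to
$\bar\Sigma$, no-spike evidence $-\zeta(1-\zeta)(\bar\gamma^+-\bar\gamma^-)$,
and state mixing with prefactors $\Omega_+(1-\zeta)/\zeta$ and
$\Omega_-\zeta/(1-\zeta)$); each observed spike of neuron $i$ applies the
first-order jumps
$\Delta\zeta = \zeta(1-\zeta)(\gamma^+_i-\gamma^-_i)/\langle\Gamma\rangle_{ii}$
and $\Delta\mu^\pm = \beta\,\Sigma^\pm e_i$; $\Sigma^\pm$ has no spike jump.
During a neuron's refractory period its likelihood contribution is omitted
($\gamma_i = \Gamma_{ii} = 0$), and $p_{rel}$ enters as the effective
threshold rate $g\,p_{rel}$, since only transmitted spikes are observable.
Independent assemblies get independent filters.

Numerical choices (all visible in `adf_step()`, the pure-R reference
implementation that the compiled filter is tested against):

* explicit Euler on the drift, jumps applied after the drift within the bin;
* $\zeta$ clipped to $[10^{-6}, 1-10^{-6}]$ to protect the mixing
  prefactors; the per-bin mixing factor $dt\,\Omega_\pm(1-\zeta)/\zeta$ is
  additionally capped at 1 (full relaxation within a bin), which only binds
  at the clip;
* $\Sigma^\pm$ symmetrized every bin; positive-semidefiniteness is a tested
  invariant rather than an enforced projection;
* the exact-Bayes multiplicative update
  $\zeta' \propto \zeta\gamma^+_i$ is available via `zeta_jump = "exact"`
  for cross-checking (both agree as $dt \to 0$);
* halving $dt$ changes response traces by well under 1% RMS for every preset
  (tested).

Readouts: `optimal_response()` low-passes
$\sum_i w_i(\zeta\mu^+_i + (1-\zeta)\mu^-_i)$ with $\tau_{post}$
($\tau_{post}=0$ is instantaneous); `rate_readout()` does the same for the
posterior expected rates; `nonlinear_readout()` estimates the posterior
expectation of a sigmoid of the weighted potential sum by one-dimensional
Monte-Carlo over the per-assembly two-component normal mixture. The sigmoid
is implemented with the exponent $e^{\beta_f x - \theta_f}$, i.e.
*decreasing* in $x$, exactly as the convention it reproduces is printed; pass
`decreasing = FALSE` for the increasing convention. We deliberately do not
silently flip the sign.

The **particle filter** (`pf_run()`) is the independent oracle: a bootstrap
filter with prior-dynamics proposals, Poisson bin likelihoods, log-weights
and systematic resampling at ESS < 50%. On the single-neuron validation
configuration the assumed-density filter agrees with a $10^4$-particle
oracle to about 0.02 posterior standard deviations (the acceptance bound is
0.2, and the oracle's own seed-to-seed spread is checked to be below that
bound, so the comparison is informative).

## Simplified dendrite models

Four integrators mirror increasing structural sophistication: `linear_model`
(identical PSPs, 3 parameters), `somatic_model` (linear dendrites, sigmoidal
soma, 5 parameters), and `subunit_model` with `random` or `clustered` wiring
(two-layer: per-branch linear integration then a sigmoid, soma averaging the
branches; clustered wiring maps each assembly to one branch and shares the 5
parameters across branches). The `reduced_optimal_model` is the analytically
motivated bridge between the filter and the dendrite: in the
switching-dominated regime the optimal response reduces to
$v \approx \bar u_- + (\bar u_+ - \bar u_-)\sigma(\nu)$ with
$\dot\nu = B\,s(t) - C$. The theory constructor `reduced_from_params()` sets
$B = \beta(\bar u_+ - \bar u_-)$ (the log likelihood ratio of one spike under
the two states at stationary statistics), $C = \bar\gamma^+ - \bar\gamma^-$
(transmitted rates), and, because finite switching rates make remote spikes
less informative, a proportional leak with rate $A = \Omega_+ + \Omega_-$
towards the prior log-odds. With nothing fitted this tracks the full filter
to within ~2% of the response range on hippocampal-like statistics; the
acceptance bound (10% RMS of the range, a package-level choice since the
source result is qualitative) leaves room for less favourable seeds.

**Fitting** (`fit_model()`) minimizes the mean squared error to a target
signal. Output gain and offset are linear given the remaining parameters and
are profiled out exactly at every objective evaluation, so the numerical
search runs over at most three parameters per (sub)unit (log time constant,
log slope, threshold), by multi-start Nelder–Mead; the per-subunit variant
uses cyclic backfitting. Initial guesses come from `reduced_from_params()`,
which in practice makes the search land in the same optimum from every
start.

**Benchmarking** (`benchmark_models()`) follows the four-assembly scenario:
per run, a 240 s training and 120 s test sequence are simulated; models are
fitted to the true equally-weighted mean of the presynaptic potentials and
scored by the fraction of variance explained on the test segment (variance
with $1/(T-1)$, MSE with $1/T$). Simulation and filtering run at
$dt = 0.5$ ms and fitting/evaluation on a 2 ms grid — the signal has a 20 ms
time constant, so this is well resolved and keeps a 10-run benchmark inside
a desk-scale compute budget. The clustered model reaches the optimal
response's run distribution (its residual deficit, under 0.01 fraction of
variance, is a model-class ceiling: the subunit cannot track within-state
per-neuron fluctuations that the filter does); linear, somatic and random
wiring lose roughly ten times more. Because the tiny clustered deficit is
*consistent* across runs, a paired test at large $n$ would eventually flag
it; the acceptance criterion compares the clustered model against the
optimal response's run *distribution* (unpaired), which is what
"indistinguishable" means here, while the clearly worse models are tested
paired.

## Fitting stimulation experiments

`protocol_to_spikes()` maps uncaging events to single presynaptic spikes
(non-responsive sites dropped); `preprocess_trace()` averages repetitions,
smooths with a Gaussian kernel ($\sigma = 0.2$ ms) and decimates 50 kHz →
2 kHz; `classify_spine()` fits the double-exponential
$\phi_0(e^{-(t-t_0)/\tau_1} - e^{-(t-t_0)/\tau_2})$ and flags a spine
non-responsive if $\tau_2 > 15$ ms or $t_0 > 5$ ms.

`fit_optimal_to_traces()` fits, jointly across the conditions of one cell,
the shared synaptic weight $w$ (profiled linearly), $\tau_{post}$ (log grid
plus refinement) and one structure parameter: the functional cluster size
$N$ for the state-switching presets (integer grid, ties towards smaller
$N$) or $\rho$ for `cor2` ($N$ fixed at stimulated + 20); `ind` has none.
That makes 2 free parameters for `ind` and 3 for the others. Predictions and
data are compared baseline-subtracted, pooled across conditions with equal
per-sample weight, and the error is normalized by the pooled variance of the
repetition-averaged data. `intrinsic_variability()` implements the
trial-to-trial floor exactly as printed (outer $1/(L-1)$, inner $1/T$,
variance $1/(T-1)$ — the asymmetry is kept deliberately), and
`bic_compare()` uses a Gaussian-residual BIC with the variance profiled out,
$-\tfrac n2\ln(\mathrm{RSS}/n) - \tfrac k2\ln n$, so that one extra
parameter at equal residuals costs $\ln(n)/2$ and a unit of difference is an
e-fold likelihood ratio.

## What the synthetic data does and does not establish

The generator *is* the statistical world the filter assumes, so green tests
establish internal consistency (correct implementation of the model, the
filter, and the fitting machinery) and the qualitative phenomena that follow
from it: additive integration for independent inputs, supralinear
integration under state switching, sublinear under pure second-order
correlations, and the benefit of clustered nonlinear subunits. They do not
establish anything about real dendrites: real recordings bring correlated
noise, electrode drift, stochastic vesicle release at each trial, and
presynaptic statistics that are themselves estimates. The synthetic
"recorded" traces used by the fitting tests add only white Gaussian noise
across repetitions and are labelled synthetic wherever they are written.

## Known limitations

* Two global states per assembly only; no smoothing (backward pass); no
  online parameter learning; no inhibitory pathway.
* The exponential link means extreme depolarisations produce per-bin spike
  probabilities near 1; the simulator warns rather than switching to an
  exact thinning scheme.
* The particle filter shares the refractory bookkeeping of the
  assumed-density filter (observation-driven clocks), so it validates the
  filtering equations, not that bookkeeping itself.
* With release probability below 1 the generator's refractory period and
  the filter's observable refractory period genuinely differ (suppressed
  spikes are invisible); this model mismatch is intentional and small at
  the preset rates.
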