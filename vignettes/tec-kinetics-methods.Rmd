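---
title: "Kinetic models and fitting methods for TEC rapid-mixing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models and fitting methods for TEC rapid-mixing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teckinetics)
```

This vignette documents the models implemented in `teckinetics`, the
assumptions behind them, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## The mechanistic setting

A transcription elongation complex (TEC) is RNA polymerase engaged with its
DNA template and nascent RNA. Rapid-mixing experiments dissect one round of
the nucleotide addition cycle: a quench-flow instrument samples the chemical
product (RNA extension, read off gels as a product fraction) at millisecond
times, while a stopped-flow fluorimeter records continuous traces from base
analogues placed in the template DNA (6-MI, quenched by a neighboring
guanine, reporting translocation and backtracking) or in the RNA (2-AP,
reporting release of a cleaved dinucleotide). A separate equilibrium setup
titrates an inhibitor or binding factor against a fluorescent TEC.

## Three-step scheme for nucleotide addition and translocation

`build_three_step_scheme()` encodes

* reversible interconversion of the starting TEC16 between an inactive and
  an active state (`k_rec`: inactive to active; `k_inact`: active to
  inactive), both in s^-1;
* irreversible nucleotide addition by the active complex (`k_add`, s^-1);
* irreversible forward translocation (`k_tr`, s^-1).

NTP dependence is folded into a single pseudo-first-order `k_add` because
the assay design uses saturating substrate (a 400 uM NTP syringe, 200 uM
after equal-volume mixing): the scheme is intended for data collected at a
single saturating substrate concentration, and a single effective rate is
what such data can support.

The initial distribution places a `slow_fraction` of complexes in the
inactive state. Two readings of this quantity are supported:

* as a free parameter of the fit (the default surface); and
* tied to the interconversion rates via
  `slow_fraction_equilibrium_tie()`, which sets
  `slow_fraction = k_inact / (k_inact + k_rec)`.

The tie is the package's recommended configuration and is what the bundled
analyses use. The rationale is mechanistic: the inactive and active states
exchange slowly and reversibly, so a TEC preparation that has been assembled
and stored before mixing sits at the equilibrium of that step — its initial
partition is not an independent degree of freedom. Practically, the free
parameterization is close to degenerate: over a finite observation window an
increase in `k_inact` can mimic a larger initial inactive fraction, and the
optimizer can trade one for the other almost freely. With the tie in place
the slow fraction is reported as a derived quantity and the degeneracy
disappears.

## Simulation

`simulate_scheme()` integrates the mass-action rate equations with a
stiff-capable solver (`deSolve::ode`, `lsoda`), relative tolerance 1e-8.
Rate constants within a single fit span more than three orders of magnitude
(0.02-93 s^-1), which is why a stiff-capable method is the default rather
than an option. The absolute tolerance is scale-aware: 1e-10 in fraction
space, and 1e-12 of the receptor pool when a scheme with tracked species is
integrated in concentration space. Schemes with a concentration-multiplied
transition (the binding scheme) are integrated in concentrations because
depletion coupling is nonlinear in fractions; fractions are recovered on
output. State fractions in `[-1e-10, 0)` are clamped to zero — solver noise
at this level must not poison downstream fits — while anything below
`-1e-10` raises an error rather than being silently repaired.

## Stretched-exponential medians

Relaxations driven by a distribution of rates (backtracking-limited
cleavage, pyrophosphorolysis) are summarized with
`signal = baseline + amplitude * (1 - exp(-(t/tau)^beta))`, amplitude signed
so that rising (2-AP) and falling (6-MI) traces are handled by the same
parameterization, never by flipping data. The reported statistic is the
median reaction time `tau * ln(2)^(1/beta)`, the time at which the fitted
curve crosses half its total amplitude; for `beta = 1` it reduces to the
half-life. Medians are preferred to `tau` itself because they remain
comparable across traces with different `beta`.

`beta` is fit freely within `(0.1, 2]` and recorded; a fit ending on a bound
is flagged rather than silently accepted. Because the objective is
multimodal in `(tau, beta)`, the fit multi-starts over
`beta in {0.5, 0.75, 1}` with `tau` initialized from the observed
half-crossing, making the result deterministic for a given trace. Residuals
are unweighted within a trace: stopped-flow noise is homoscedastic to a good
approximation, and no per-point variance information exists for a single
trace. A trace whose total spread is within twice the first-difference noise
estimate is rejected as constant — with no resolvable amplitude there is no
median to report.

## Global fitting and profile bounds

`fit_global()` minimizes one joint chi-square over all observations —
quench-flow point series and stopped-flow traces together — with shared rate
constants. "Combined analysis of several independent experiments" is
implemented exactly this way: replicates enter as additional observations,
and each fluorescence trace carries its own scale and offset, profiled
analytically (weighted linear least squares on the projected signal basis)
at every objective evaluation. Direction of a fluorescence change lives in
the sign of the observable coefficients.

Weighting: each observation's residuals are divided by its measurement SD.
Synthetic traces carry their generating SD; for real data without one, a
pilot fit is run and the SD of late-time residuals (final 20% of the time
range, minimum 4 points) is used, on the reasoning that late times are
closest to plateau and dominated by instrument noise. Quench-flow points
within one series share a single SD (equal weights).

Optimization is Levenberg-Marquardt (`minpack.lm`) on log10-transformed
rates (box-bounded to 10^-6 to 10^8 s^-1) and natural-scale fraction
parameters bounded to [0, 1]. The objective is multimodal — sequential
mechanisms admit rate-swapped local minima — so the fit multi-starts from a
deterministic, truth-agnostic set: the user's initial values; all free rates
at a common magnitude 10^g for g in {-1, 0, 1, 2}; and split starts with the
first half of the free rates at 10^g1 and the second half at 10^g2 for every
ordered pair g1 != g2. The split starts matter: mechanisms whose catalytic
and conformational-exchange rates live on different scales are reached from
them when the all-equal starts stall in a fast-exchange minimum. Additional
starts, if requested, are seeded log-uniform draws from a self-contained
generator, so fitting never perturbs the caller's RNG stream. Parameters
whose perturbation leaves every residual unchanged are flagged as
structurally unidentifiable.

`profile_bounds()` reports, per free parameter, the interval over which the
re-optimized chi-square (all other parameters refit) stays within a chosen
fractional increase — 10% by default — of the minimum. Endpoints are
bracketed geometrically and bisected to 1% relative precision; a profile
still under the threshold after a factor of 1000 from the best fit is
flagged unbounded on that side. This is a practitioner's confidence region
in the FitSpace tradition, not an asymptotic covariance: it is honest about
asymmetry and non-identifiability, which the three-step scheme exhibits (the
recovery rate is constrained only by the small slow-phase amplitude in the
quench-flow data, and its interval spans roughly an order of magnitude).

## Binding kinetics with explicit depletion

`fit_binding_series()` fits stopped-flow binding traces at several post-mix
ligand concentrations jointly to the one-step reversible scheme, with the
free ligand computed from conservation at every instant. Depletion handling
is mandatory, not optional: at the lowest post-mix concentration (0.1 uM
ligand vs 0.2 uM receptor) the pseudo-first-order approximation is badly
wrong. At least three distinct concentrations are required — with a single
concentration the association and dissociation rates are not separable from
one observed relaxation rate. `Kd = k_minus1 / k_plus1` is derived from the
fit.

## Depletion-corrected titrations

`bound_fraction()` evaluates the physical root of
`b^2 - (R + L + Kd) b + R L = 0` in the numerically stable form that avoids
cancellation at small `Kd`. `fit_titration()` optimizes a shared `log10(Kd)`
(positivity by construction) with per-curve signal endpoints profiled
linearly, jointly across curves. The 95% confidence interval is computed by
profiling the joint residual sum of squares against an F-threshold;
small-sample duplicate designs make Wald intervals unreliable, so the
profile interval is primary, with the Wald interval reported alongside for
comparison. Curves whose best-fit maximum bound fraction stays below 0.5 are
flagged: a titration that never spans its transition cannot pin `Kd` from
above. Sequential-addition dilution is supported through optional cumulative
volumes but defaults to off, since addition volumes are typically not
recorded per step.

Whether two independent titrations should be fit jointly or averaged as two
separate estimates is genuinely ambiguous in practice; the package fits them
jointly (shared `Kd`, separate endpoints), which uses the data more
efficiently and is the configuration the confidence interval describes.

## Synthetic data: what is and is not emulated

The generators produce every input class the pipeline consumes, seeded and
bit-reproducible, via a self-contained uniform/Box-Muller generator:

* quench-flow product series: 12 log-spaced points over 0.004-10 s, the
  instrument's sampling window;
* stopped-flow traces: dense sampling after a 1.5 ms dead time (uniform by
  default; log-spaced for experiments spanning well-separated timescales —
  real instruments use split time bases for the same reason);
* binding series: traces at post-mix concentrations equal to half the
  syringe values, reflecting equal-volume mixing, with the mixing
  bookkeeping done once in the generator;
* titrations: equilibrium signals at 100 nM receptor.

Noise is additive Gaussian, homoscedastic per trace, with SD defaulting to
1% (stopped flow) and 2% (quench flow) of the full signal amplitude. These
defaults are declared assumptions: published figures show scatter consistent
with them, but the true noise magnitude and autocorrelation of any given
instrument are unknown. Not emulated: photobleaching, inner-filter effects,
instrument drift, heteroscedastic or correlated noise, and gel-quantification
artifacts. Passing round-trip tests therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
pathology of real instrument data.

The condition presets (`condition_presets()`) carry per-condition median
reaction times for the cleavage and pyrophosphorolysis assays and generate
backtracking-limited traces: `k_bt = ln(2) / median`, cleavage 100-fold
faster, return rate zero, so the observable is single-exponential to within
about 1%. Presets are single-exponential targets because a median alone does
not determine a shape; a `beta` can be supplied where stretched shapes are
wanted. The backtracking return rate `k_fwd` is exposed in the scheme but
defaults to zero in the presets: when cleavage is much faster than
backtracking, a backtracked complex is cleaved before it can return, so the
data contain no information about `k_fwd`.

## Reference experiment designs and problem sizes

The bundled dual-observable experiment (`generate_three_step_dataset()`)
uses two quench-flow replicates (12 points each) and two stopped-flow
replicates (250 points each, log-spaced over 1 s). The stopped-flow window
is deliberately short: it is the fast-phase timebase, chosen to resolve
nucleotide addition and translocation (half-times of 10-25 ms), while the
slow inactive-fraction recovery is left to the quench-flow window (to 10 s).
A long fluorescence window would over-constrain the recovery rate and hide
the weak identifiability that is a genuine feature of this design. The
binding series uses six syringe concentrations spanning 0.2-20 uM (post-mix
0.1-10 uM), 250 points per trace; titrations use nine ligand levels spanning
0-3.2 uM around a 0.12 uM dissociation constant. These sizes keep a full
analysis — global fit, profile bounds, binding and titration fits — in the
minutes range on a single core.

## Known limitations

* No stochastic (Gillespie) simulation and no spatial modelling; schemes are
  deterministic mass action with at most one concentration multiplier per
  transition, and no thermodynamic cycle-closure checks are performed.
* The global optimizer guarantees a careful local search from a documented
  multi-start set, not a global optimum certificate.
* Profile bounds assume the chi-square surface is explored adequately by
  re-optimizing the remaining parameters from the best fit; pathological
  multimodality inside the profile could in principle be missed.
* No model selection between stretched- and multi-exponential forms is
  attempted; the stretched form is a summary device, not a mechanistic
  claim.
* Cooperative or multi-site binding is out of scope for the titration model.
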