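# teckinetics

Pre-steady-state kinetic analysis of RNA polymerase transcription elongation
complexes (TECs) in R: mass-action scheme simulation, global fitting of
quench-flow and stopped-flow data, profile-based parameter bounds,
stretched-exponential median reaction times, and depletion-corrected
equilibrium binding.

The package targets the kind of rapid-mixing study in which the effect of a
transcription factor (here, NusG) on elongation is dissected into on-pathway
steps (nucleotide addition, translocation), off-pathway steps (backtracking,
probed via cleavage-factor-assisted RNA cleavage), and factor binding itself.
Because such studies rarely deposit raw instrument traces, the package ships
seeded synthetic-data generators that emulate each assay class, so the whole
analysis pipeline is testable end to end.

## Models

**Three-step nucleotide addition / translocation.** The resting TEC16
interconverts slowly and reversibly between inactive and active states
(recovery rate k_rec, inactivation rate k_inact); the active complex extends
its RNA irreversibly at the pseudo-first-order rate k_add (saturating NTP)
and then translocates forward irreversibly at k_tr:

    TEC16_inactive  <-->  TEC16_active  -->  TEC17_pre  -->  TEC17_post
                k_rec / k_inact        k_add          k_tr

Quench-flow gel data report the product fraction (TEC17_pre + TEC17_post);
stopped-flow fluorescence reports translocation (TEC17_post). Both are fit
simultaneously by numerical integration, with per-trace fluorescence
scale/offset nuisances profiled analytically. Parameter confidence bounds
are FitSpace-style: the interval over which the re-optimized chi-square
stays within a 10% increase of its minimum.

**Stretched-exponential relaxations.** Backtracking, cleavage,
dinucleotide-release and pyrophosphorolysis traces are summarized by fitting
`baseline + amplitude * (1 - exp(-(t/tau)^beta))` and reporting the median
reaction time `tau * ln(2)^(1/beta)` — the half-amplitude crossing time,
which generalizes the half-life to beta != 1.

**One-step reversible binding with depletion.** Factor binding traces at
several concentrations are fit jointly to
`TEC_free + L <--> TEC_bound` (k_+1, k_-1) with the free ligand tracked as a
conserved species, valid when ligand and receptor concentrations are
comparable; Kd = k_-1 / k_+1 is derived.

**Depletion-corrected titrations.** Equilibrium titrations at 100 nM
receptor are fit with the quadratic mass-balance bound fraction (the
physical root of `b^2 - (R + L + Kd) b + R L = 0`), shared Kd across curves,
and a profile-likelihood 95% confidence interval.

## Worked example

```r
library(teckinetics)

# the reference rate constants; the slow fraction is the equilibrium of the
# inactivation step
truth <- c(k_add = 28, k_tr = 65, k_rec = 1.1, k_inact = 0.09)
truth["slow_fraction"] <- truth[["k_inact"]] / (truth[["k_inact"]] + truth[["k_rec"]])

scheme <- build_three_step_scheme()
dataset <- generate_three_step_dataset(truth, seed = 1)   # 2 QF + 2 SF replicates
fit <- fit_global(dataset, scheme,
                  c(k_add = 10, k_tr = 10, k_rec = 1, k_inact = 0.1,
                    slow_fraction = 0.1),
                  ties = slow_fraction_equilibrium_tie())
fit$bounds <- profile_bounds(fit, dataset, scheme, chi2_increase = 0.10)
print(fit)
```

```
Global fit (scheme 'three_step'): chi2 = 521.62, converged = TRUE, iterations = 15
  k_add          27.5436
  k_tr           67.6946
  k_rec          1.07212
  k_inact        0.0858524
  Profile bounds (chi2 + 10 %):
 parameter       lower        best      upper lower_unbounded upper_unbounded
     k_add 24.94389330 27.54360610 31.0917725           FALSE           FALSE
      k_tr 56.13388338 67.69461828 80.4459991           FALSE           FALSE
     k_rec  0.46244386  1.07211760  3.6953201           FALSE           FALSE
   k_inact  0.03517575  0.08585238  0.2271666           FALSE           FALSE
```

The fit recovers the generating constants (nucleotide addition 27.5 s^-1,
translocation 67.7 s^-1, slow TEC fraction 7.4%) and exposes the weak
identifiability of the inactive-state exchange rates: the recovery-rate
interval spans almost an order of magnitude even though the catalytic rates
are pinned to within ~15%.

A stretched-exponential median in two lines:

```r
trace <- generate_stopped_flow_trace(preset_spec("WT-2AP", seed = 7))
fit_stretched_exponential(trace)
#> Stretched-exponential fit: tau = 17.91 s, beta = 1.004, amplitude = 1.009
#>   median reaction time = 12.43 s (rss = 0.0461, n = 500)
```

## Command line

A thin wrapper is installed at
`system.file("cli", "teckin", package = "teckinetics")` with subcommands
`simulate`, `synth`, `median`, `fit`, `profile`, `titrate` and `bind`; see
`?cli_main`.
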