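# Seeded Gaussian noise drawn from a self-contained generator so synthetic
# data are bit-reproducible per (spec, seed) and never disturb the caller's
# RNG stream. Box-Muller on the multiplicative-congruential stream.
.seeded_gauss <- function(seed) {
  rng <- .seeded_rng(seed)
  cache <- NULL
  rnormn <- function(n, sd = 1) {
    out <- numeric(n)
    i <- 1L
    while (i <= n) {
      if (!is.null(cache)) {
        out[i] <- cache; cache <<- NULL; i <- i + 1L; next
      }
      u1 <- rng$unif(0, 1); u2 <- rng$unif(0, 1)
      if (u1 <= 1e-300) u1 <- 1e-300
      r <- sqrt(-2 * log(u1))
      out[i] <- r * cos(2 * pi * u2)
      cache <<- r * sin(2 * pi * u2)
      i <- i + 1L
    }
    out * sd
  }
  rnormn
}

.logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Describe a synthetic experiment
#'
#' A generator spec bundles everything needed to emulate one assay: the
#' scheme, the rate parameters, the assay kind, the sampling design, the
#' noise level and the seed. Defaults reproduce the reference designs:
#' 12 log-spaced quench-flow points over 0.004-10 s with 2% amplitude noise,
#' and dense stopped-flow traces after a 1.5 ms dead time with 1% amplitude
#' noise.
#'
#' @param scheme scheme name (`"three_step"`, `"bimolecular_binding"`,
#'   `"backtrack_cleavage"`) or a `kinetic_scheme`.
#' @param params named rate-parameter vector for the scheme.
#' @param assay one of `"quench_flow"`, `"stopped_flow"`, `"titration"`,
#'   `"binding_series"`.
#' @param design list overriding the sampling design: `t_min`, `t_max`
#'   (seconds), `n_points`, `spacing` (`"uniform"` or `"log"`; stopped-flow
#'   default uniform), `dead_time` (seconds, stopped-flow default 0.0015).
#' @param noise Gaussian SD as a fraction of the full signal amplitude
#'   (default 0.02 for quench flow, 0.01 otherwise).
#' @param seed integer seed; recorded in every output.
#' @param conditions condition record (post-mix molar concentrations etc.).
#' @param observable an [observable_map()]; defaults to the natural read-out
#'   of the scheme (product fraction for `three_step`, cleaved-state
#'   fluorescence for `backtrack_cleavage`, bound-state fluorescence for
#'   `bimolecular_binding`).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(scheme = "three_step", params,
                           assay = c("quench_flow", "stopped_flow",
                                     "titration", "binding_series"),
                           design = list(), noise = NULL, seed = 1,
                           conditions = list(), observable = NULL) {
  assay <- match.arg(assay)
  if (assay == "titration") {
    scheme <- NULL  # equilibrium assay: no kinetic scheme involved
  } else if (is.character(scheme)) {
    scheme <- .scheme_registry(scheme)
  }
  noise <- noise %||% if (assay == "quench_flow") 0.02 else 0.01
  if (noise < 0) stop_teckin("teckin_bad_noise", "noise must be >= 0")
  d <- switch(assay,
    quench_flow = list(t_min = 0.004, t_max = 10, n_points = 12,
                       spacing = "log", dead_time = 0),
    stopped_flow = list(t_min = NA, t_max = 10, n_points = 500,
                        spacing = "uniform", dead_time = 0.0015),
    list(t_min = NA, t_max = NA, n_points = NA, spacing = NA, dead_time = 0))
  d[names(design)] <- design
  if (!is.na(d$t_max) && !is.na(d$dead_time) && d$t_max <= d$dead_time)
    stop_teckin("teckin_bad_design", "duration must exceed the dead time")
  if (is.null(observable) && !is.null(scheme)) {
    observable <- switch(scheme$name,
      three_step = observable_map("state_sum",
                                  states = c("TEC17_pre", "TEC17_post")),
      backtrack_cleavage = observable_map("fluorescence",
                                          coefficients = c(TEC_cleaved = 1)),
      bimolecular_binding = observable_map("fluorescence",
                                           coefficients = c(TEC_bound = 1)),
      NULL)
  }
  structure(list(scheme = scheme, params = params, assay = assay,
                 design = d, noise = noise, seed = as.integer(seed),
                 conditions = conditions, observable = observable),
            class = "generator_spec")
}

.stamp <- function(df, spec, extra = list()) {
  attr(df, "seed") <- spec$seed
  attr(df, "scheme") <- spec$scheme$name %||% NA_character_
  attr(df, "assay") <- spec$assay
  attr(df, "noise") <- spec$noise
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  df
}

#' Generate a quench-flow product time course
#'
#' Simulates the scheme, projects the product-fraction observable at
#' log-spaced times within the instrument window (0.004-10 s by default)
#' and adds seeded Gaussian noise scaled to the full amplitude of the
#' noiseless curve.
#'
#' @param spec a [generator_spec()] with `assay = "quench_flow"`.
#' @return data frame `time_s`, `signal`, `sigma` with provenance
#'   attributes (`seed`, `scheme`, `assay`, `noise`).
#' @export
generate_quench_flow <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), spec$assay == "quench_flow")
  d <- spec$design
  times <- .logspace(d$t_min, d$t_max, d$n_points)
  traj <- simulate_scheme(spec$scheme, spec$params, times, spec$conditions)
  clean <- project_observable(traj, spec$observable)
  amp <- diff(range(clean)); if (amp == 0) amp <- 1
  sd_abs <- spec$noise * amp
  y <- clean + .seeded_gauss(spec$seed)(length(clean), sd_abs)
  .stamp(data.frame(time_s = times, signal = y, sigma = sd_abs), spec)
}

#' Generate a stopped-flow fluorescence trace
#'
#' Dense sampling after the instrument dead time (uniform by default; log
#' spacing available for experiments spanning well-separated timescales),
#' fluorescence projection with the spec's observable scale and offset, and
#' seeded Gaussian noise scaled to the full amplitude of the noiseless
#' trace.
#'
#' @param spec a [generator_spec()] with `assay = "stopped_flow"`.
#' @return data frame `time_s`, `signal`, `sigma` with provenance
#'   attributes, including `dead_time_s`.
#' @export
generate_stopped_flow_trace <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), spec$assay == "stopped_flow")
  d <- spec$design
  t0 <- if (!is.na(d$t_min) && d$t_min >= d$dead_time) d$t_min else d$dead_time
  times <- if (identical(d$spacing, "log")) .logspace(t0, d$t_max, d$n_points)
           else seq(t0, d$t_max, length.out = d$n_points)
  traj <- simulate_scheme(spec$scheme, spec$params, times, spec$conditions)
  clean <- project_observable(traj, spec$observable)
  amp <- diff(range(clean))
  # zero-contrast observables (solver wiggle only): noise scales to the
  # signal level instead, yielding an honest flat noisy trace
  if (amp <= 1e-8 * max(abs(clean), 1)) amp <- max(abs(clean), 1)
  sd_abs <- spec$noise * amp
  y <- clean + .seeded_gauss(spec$seed)(length(clean), sd_abs)
  .stamp(data.frame(time_s = times, signal = y, sigma = sd_abs), spec,
         extra = list(dead_time_s = d$dead_time))
}

#' Generate a bimolecular binding concentration series
#'
#' One stopped-flow trace per ligand concentration from the one-step
#' reversible binding scheme with explicit depletion. Concentrations are
#' supplied as syringe values; post-mix concentrations are half the syringe
#' values (equal volumes of the receptor and ligand solutions are mixed)
#' and are recorded in the trace metadata.
#'
#' @param spec a [generator_spec()] with `assay = "binding_series"` and
#'   scheme `bimolecular_binding`; `spec$conditions$receptor_syringe_M`
#'   gives the receptor syringe concentration (default 4e-7, i.e. 0.4 uM).
#' @param ligand_syringe_M numeric vector of ligand syringe concentrations
#'   (molar).
#' @return list of trace data frames, each with attributes
#'   `ligand_total_M`, `receptor_total_M` (post-mix), `ligand_syringe_M`,
#'   `dead_time_s`, `seed`.
#' @export
generate_binding_series <- function(spec, ligand_syringe_M) {
  stopifnot(inherits(spec, "generator_spec"), spec$assay == "binding_series")
  if (!length(ligand_syringe_M))
    stop_teckin("teckin_empty_input", "need >= 1 ligand concentration")
  R_syr <- spec$conditions$receptor_syringe_M %||% 4e-7
  R <- R_syr / 2
  d <- spec$design
  t_max <- if (is.na(d$t_max)) 2 else d$t_max
  n_pts <- if (is.na(d$n_points)) 400 else d$n_points
  dead <- if (is.na(d$dead_time)) 0.0015 else max(d$dead_time, 0.0015)
  lapply(seq_along(ligand_syringe_M), function(i) {
    L <- ligand_syringe_M[i] / 2
    sub <- spec
    sub$assay <- "stopped_flow"
    sub$design <- list(t_min = NA, t_max = t_max, n_points = n_pts,
                       spacing = "log", dead_time = dead)
    sub$conditions <- list(receptor_total = R,
                           species_totals = c(ligand = L))
    sub$seed <- spec$seed + i - 1L
    tr <- generate_stopped_flow_trace(sub)
    attr(tr, "ligand_total_M") <- L
    attr(tr, "receptor_total_M") <- R
    attr(tr, "ligand_syringe_M") <- ligand_syringe_M[i]
    tr
  })
}

#' Generate an equilibrium titration curve
#'
#' Equilibrium signals from [titration_model()] at the requested total
#' ligand levels with seeded Gaussian noise.
#'
#' @param spec a [generator_spec()] with `assay = "titration"`;
#'   `spec$params` must contain `Kd` (molar); `spec$conditions` may set
#'   `receptor_total` (default 1e-7, the 100 nM design),
#'   `signal_free` (default 1) and `signal_bound` (default 0.5, a
#'   fluorescence quench upon binding).
#' @param ligand_levels_M nondecreasing total ligand concentrations (molar).
#' @return a [titration_curve()] with provenance attributes.
#' @export
generate_titration <- function(spec, ligand_levels_M) {
  stopifnot(inherits(spec, "generator_spec"), spec$assay == "titration")
  if (is.unsorted(ligand_levels_M))
    stop_teckin("teckin_bad_titration", "ligand levels must be nondecreasing")
  R <- spec$conditions$receptor_total %||% 1e-7
  sf <- spec$conditions$signal_free %||% 1
  sb <- spec$conditions$signal_bound %||% 0.5
  kd <- spec$params[["Kd"]]
  cu <- titration_curve(ligand_levels_M, rep(0, length(ligand_levels_M)), R)
  clean <- titration_model(cu, kd, sf, sb)
  amp <- abs(sb - sf); if (amp == 0) amp <- 1
  y <- clean + .seeded_gauss(spec$seed)(length(clean), spec$noise * amp)
  out <- titration_curve(ligand_levels_M, y, R)
  .stamp(out, spec)
}

#' Generate the dual-observable three-step experiment
#'
#' Builds the combined dataset of the nucleotide-addition / translocation
#' experiment: quench-flow product-fraction points (12 log-spaced times over
#' 0.004-10 s, 2% amplitude noise) and stopped-flow translocation
#' fluorescence traces (post-translocated-state signal, log-spaced over
#' 1 s after the 1.5 ms dead time, 1% amplitude noise), in replicate.
#' The stopped-flow window targets the fast nucleotide-addition and
#' translocation phases; the slow inactive-fraction recovery is covered by
#' the quench-flow window. All replicates share the rate parameters in the
#' joint fit; fluorescence traces carry per-trace scale/offset nuisances.
#'
#' @param params three-step rate parameters (`k_add`, `k_tr`, `k_rec`,
#'   `k_inact`, `slow_fraction`).
#' @param seed base integer seed; replicate r of observation class c uses
#'   `seed + 100 * c + r`.
#' @param n_qf,n_sf number of quench-flow and stopped-flow replicates
#'   (default 2 each, the duplicate design).
#' @param sf_t_max,sf_n stopped-flow window (seconds) and points per trace.
#' @param noise_qf,noise_sf fractional amplitude noise per assay.
#' @return a [kinetic_dataset()] ready for [fit_global()] against
#'   [build_three_step_scheme()].
#' @export
generate_three_step_dataset <- function(params, seed = 1, n_qf = 2, n_sf = 2,
                                        sf_t_max = 1, sf_n = 250,
                                        noise_qf = 0.02, noise_sf = 0.01) {
  obs <- list()
  for (r in seq_len(n_qf)) {
    qf <- generate_quench_flow(generator_spec(
      "three_step", params, "quench_flow", noise = noise_qf,
      seed = seed + 100 + r))
    obs[[length(obs) + 1]] <- kin_observation(
      qf, observable_map("state_sum", states = c("TEC17_pre", "TEC17_post")),
      label = paste0("quench_flow_", r))
  }
  for (r in seq_len(n_sf)) {
    sf <- generate_stopped_flow_trace(generator_spec(
      "three_step", params, "stopped_flow", noise = noise_sf,
      design = list(spacing = "log", t_max = sf_t_max, n_points = sf_n),
      observable = observable_map("fluorescence",
                                  coefficients = c(TEC17_post = 1),
                                  scale = 2, offset = 0.5),
      seed = seed + 200 + r))
    obs[[length(obs) + 1]] <- kin_observation(
      sf, observable_map("fluorescence", coefficients = c(TEC17_post = 1)),
      conditions = list(dead_time = 0.0015),
      label = paste0("stopped_flow_", r))
  }
  kinetic_dataset(obs)
}

#' Reference condition presets: median reaction times
#'
#' The per-condition median reaction times (seconds) used as round-trip
#' targets by the synthetic generators: RNA-cleavage (2-AP dinucleotide
#' release) medians for the wild-type and altered TECs with and without
#' NusG, and the pyrophosphorolysis medians. `mm` denotes a DNA:DNA
#' mismatch; `3'mm` a mismatch against the 3' RNA nucleotide; `dRL`, `dLL`,
#' `dGL` deletions of polymerase domains.
#'
#' @return data frame with columns `label`, `assay`, `nusg` (`"-"`/`"+"`),
#'   `median_s`, `beta` (presets are single-exponential targets, beta = 1).
#' @export
condition_presets <- function() {
  p <- rbind(
    data.frame(label = "WT",    nusg = c("-", "+"), median_s = c(12.4, 30.3)),
    data.frame(label = "dRL",   nusg = c("-", "+"), median_s = c(11.1, 25.7)),
    data.frame(label = "dLL",   nusg = c("-", "+"), median_s = c(11.4, 20.6)),
    data.frame(label = "dGL",   nusg = c("-", "+"), median_s = c(24.0, 54.1)),
    data.frame(label = "mm1",   nusg = c("-", "+"), median_s = c(19.9, 42.9)),
    data.frame(label = "mm1-2", nusg = c("-", "+"), median_s = c(2.30, 3.11)),
    data.frame(label = "3'mm",  nusg = c("-", "+"), median_s = c(0.34, 0.36)))
  p$assay <- "2AP"
  pyro <- data.frame(label = "pyrophosphorolysis", nusg = c("-", "+"),
                     median_s = c(0.49, 0.51), assay = "6MI")
  out <- rbind(p, pyro)
  out$beta <- 1
  out[, c("label", "assay", "nusg", "median_s", "beta")]
}

#' Generator spec targeting a condition preset
#'
#' Builds a stopped-flow generator on the backtracking-limited cleavage
#' scheme whose trace has a chosen preset's median reaction time: the
#' backtracking step is rate limiting (`k_bt = log(2) / median`,
#' `k_cleave = 100 * k_bt`, `k_fwd = 0`), so the projected trace is
#' single-exponential to within 1%. 2-AP presets rise (cleaved-state
#' signal); 6-MI/pyrophosphorolysis presets fall (loss of the starting
#' state's signal).
#'
#' @param preset preset identifier: a `label` from [condition_presets()],
#'   optionally suffixed with the assay (`"WT-2AP"`) and/or `"+NusG"`
#'   (`"WT-2AP+NusG"`); bare labels default to the `-NusG` condition.
#' @param seed integer seed.
#' @param noise fractional amplitude noise (default 0.01).
#' @param n_points,duration sampling design; duration defaults to 6x the
#'   target median so the trace spans the transition.
#' @return a [generator_spec()] ready for [generate_stopped_flow_trace()],
#'   with attribute `target_median_s`.
#' @export
preset_spec <- function(preset, seed = 1, noise = 0.01, n_points = 500,
                        duration = NULL) {
  presets <- condition_presets()
  nusg <- if (grepl("\\+NusG$", preset)) "+" else "-"
  key <- sub("\\+NusG$", "", preset)
  key <- sub("-(2AP|6MI)$", "", key)
  row <- presets[presets$label == key & presets$nusg == nusg, ]
  if (!nrow(row))
    stop_teckin("teckin_unknown_preset",
                paste0("unknown condition preset '", preset, "'"))
  med <- row$median_s[1]
  k_bt <- log(2) / med
  falling <- row$assay[1] == "6MI"
  obs <- if (falling)
    observable_map("fluorescence", coefficients = c(TEC_pre = 1))
  else
    observable_map("fluorescence", coefficients = c(TEC_cleaved = 1))
  duration <- duration %||% (6 * med)
  spec <- generator_spec(
    scheme = "backtrack_cleavage",
    params = c(k_bt = k_bt, k_fwd = 0, k_cleave = 100 * k_bt),
    assay = "stopped_flow",
    design = list(t_max = duration, n_points = n_points),
    noise = noise, seed = seed, observable = obs)
  attr(spec, "target_median_s") <- med
  spec
}
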