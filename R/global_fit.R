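#' Build one observation of a heterogeneous kinetic dataset
#'
#' An observation pairs a measured series (quench-flow product points or a
#' stopped-flow trace) with the observable that produced it and the
#' experimental conditions under which it was collected. Points earlier than
#' the stopped-flow dead time are excluded at construction: the instrument
#' delivers no valid signal before mixing completes.
#'
#' @param data data frame with columns `time_s`, `signal` and optionally
#'   `sigma` (per-point measurement SD).
#' @param observable an [observable_map()].
#' @param conditions list of condition metadata: post-mix concentrations
#'   (`receptor_total`, `species_totals`, molar), `dead_time` (seconds,
#'   default 0 i.e. no truncation).
#' @param sigma optional scalar measurement SD used when `data$sigma` is
#'   absent.
#' @param label optional identifier used in reports.
#' @return object of class `kin_observation`.
#' @export
kin_observation <- function(data, observable, conditions = list(),
                            sigma = NULL, label = NULL) {
  stopifnot(is.data.frame(data), all(c("time_s", "signal") %in% names(data)))
  dead <- conditions$dead_time %||% 0
  if (dead > 0) data <- data[data$time_s >= dead, , drop = FALSE]
  if (!nrow(data))
    stop_teckin("teckin_empty_observation", "no points remain after dead-time cut")
  conc <- c(conditions$receptor_total %||% numeric(),
            conditions$species_totals %||% numeric())
  if (length(conc) && any(conc < 0))
    stop_teckin("teckin_negative_concentration", "concentrations must be >= 0")
  structure(list(data = data, observable = observable,
                 conditions = conditions, sigma = sigma, label = label),
            class = "kin_observation")
}

#' Bundle observations into a dataset for global fitting
#'
#' @param ... `kin_observation` objects (or a single list of them).
#' @return object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(...) {
  obs <- list(...)
  if (length(obs) == 1 && !inherits(obs[[1]], "kin_observation")) obs <- obs[[1]]
  if (!length(obs)) stop_teckin("teckin_empty_dataset", "need >= 1 observation")
  ok <- vapply(obs, inherits, logical(1), "kin_observation")
  if (!all(ok)) stop_teckin("teckin_bad_observation",
                            "all elements must be kin_observation objects")
  structure(obs, class = "kinetic_dataset")
}

.obs_sigma <- function(obs) {
  s <- obs$data$sigma %||% obs$sigma %||% 1
  s <- rep_len(s, nrow(obs$data))
  if (any(s <= 0))
    stop_teckin("teckin_nonpositive_variance",
                "observation variance must be strictly positive")
  s
}

# Predicted signal for one observation; for fluorescence observables the
# per-trace scale and offset are profiled analytically (weighted linear
# least squares on the projected basis) unless fixed values are supplied.
.obs_predict <- function(obs, scheme, params, nuisance = NULL) {
  traj <- simulate_scheme(scheme, params, obs$data$time_s, obs$conditions)
  if (obs$observable$kind == "state_sum")
    return(list(pred = project_observable(traj, obs$observable),
                scale = NA_real_, offset = NA_real_))
  base_obs <- obs$observable
  base_obs$scale <- 1; base_obs$offset <- 0
  base <- project_observable(traj, base_obs)
  if (!is.null(nuisance)) {
    return(list(pred = nuisance$offset + nuisance$scale * base,
                scale = nuisance$scale, offset = nuisance$offset))
  }
  w <- 1 / .obs_sigma(obs)^2
  y <- obs$data$signal
  sw <- sum(w); sx <- sum(w * base); sy <- sum(w * y)
  sxx <- sum(w * base^2); sxy <- sum(w * base * y)
  den <- sw * sxx - sx^2
  if (abs(den) < 1e-300 * max(1, sw * sxx)) {
    scale <- 0; offset <- sy / sw  # flat basis: only the offset is defined
  } else {
    scale <- (sw * sxy - sx * sy) / den
    offset <- (sy - scale * sx) / sw
  }
  list(pred = offset + scale * base, scale = scale, offset = offset)
}

#' Global chi-square of a parameter set against a dataset
#'
#' Sum over all observations of squared residuals divided by the
#' per-observation variance. Per-trace fluorescence scale/offset nuisances
#' are profiled out analytically, so the value depends only on the rate
#' parameters.
#'
#' @param params named numeric parameter vector (see [simulate_scheme()]).
#' @param dataset a [kinetic_dataset()].
#' @param scheme the shared `kinetic_scheme`.
#' @param nuisances optional list (one element per observation) of fixed
#'   `list(scale, offset)` values; default profiles them.
#' @param ties optional named list of functions deriving a parameter from
#'   the others (e.g. [slow_fraction_equilibrium_tie()]); applied before
#'   simulation.
#' @return chi-square (dimensionless), with attribute `per_observation`.
#' @export
chi_squared <- function(params, dataset, scheme, nuisances = NULL, ties = NULL) {
  params <- .apply_ties(params, ties)
  per <- numeric(length(dataset))
  for (i in seq_along(dataset)) {
    obs <- dataset[[i]]
    pr <- .obs_predict(obs, scheme, params, nuisance = nuisances[[i]] %||% NULL)
    per[i] <- sum(((obs$data$signal - pr$pred) / .obs_sigma(obs))^2)
  }
  structure(sum(per), per_observation = per)
}

.apply_ties <- function(params, ties) {
  for (nm in names(ties %||% list())) params[[nm]] <- ties[[nm]](params)
  params
}

.residual_vector <- function(params, dataset, scheme, ties = NULL) {
  params <- .apply_ties(params, ties)
  unlist(lapply(dataset, function(obs) {
    pr <- .obs_predict(obs, scheme, params)
    (obs$data$signal - pr$pred) / .obs_sigma(obs)
  }), use.names = FALSE)
}

# parameter transform: rates are fit on log10 scale (positivity, dynamic
# range); initial-fraction parameters stay on the natural scale in [0, 1].
.theta_pack <- function(params, free, fraction_names) {
  vapply(free, function(p)
    if (p %in% fraction_names) params[[p]] else log10(params[[p]]), numeric(1))
}
.theta_unpack <- function(theta, free, params, fraction_names) {
  for (i in seq_along(free)) {
    p <- free[i]
    params[[p]] <- if (p %in% fraction_names) theta[i] else 10^theta[i]
  }
  params
}

#' Simultaneous least-squares fit of a kinetic dataset
#'
#' Fits shared rate constants (and initial-fraction parameters such as the
#' slow TEC fraction) to all observations at once by minimizing the global
#' chi-square with a derivative-based Levenberg-Marquardt optimizer.
#' Per-trace fluorescence scale/offset nuisances are profiled analytically
#' at every step ("combined analysis of several independent experiments" is
#' one joint objective with shared rates and per-replicate nuisances).
#' Rates are optimized on a log scale; fraction parameters are box-bounded
#' to `[0,1]`.
#'
#' Multi-start: the supplied initial parameters plus `n_starts - 1` seeded
#' draws from a truth-agnostic log-uniform grid (rates in `10^[-2, 3]` per
#' second, fractions uniform in `[0, 0.5]`); the start reaching the lowest
#' chi-square wins.
#'
#' When any observation lacks a measurement SD, a pilot unweighted fit is
#' run and each such observation's SD is set to the standard deviation of
#' its late-time pilot residuals (final 20% of the time range, minimum 4
#' points) before the definitive fit.
#'
#' @param dataset a [kinetic_dataset()].
#' @param scheme the shared `kinetic_scheme`.
#' @param init_params full named starting parameter vector.
#' @param free names of parameters to optimize (default: all in
#'   `init_params` that the scheme uses).
#' @param n_starts number of multi-starts (>= 1).
#' @param seed integer seed for the multi-start draws.
#' @param maxiter per-start iteration cap.
#' @return object of class `global_fit`: `params` (full best-fit vector),
#'   `free`, `chi2`, `nuisances`, `converged`, `info`, `niter`,
#'   `unidentifiable` (free parameters with zero residual sensitivity),
#'   `bounds` (filled by [profile_bounds()]).
#' @export
fit_global <- function(dataset, scheme, init_params,
                       free = intersect(names(init_params), rate_parameters(scheme)),
                       n_starts = 17, seed = 1, maxiter = 200, ties = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"), length(free) >= 1)
  free <- setdiff(free, names(ties %||% list()))
  fraction_names <- unname(scheme$initial_params %||% character())
  # box bounds on the optimization scale: fractions in [0,1], log10-rates in
  # [-6, 8] (keeps probe rates inside the solver's comfortable range)
  lower <- ifelse(free %in% fraction_names, 0, -6)
  upper <- ifelse(free %in% fraction_names, 1, 8)

  needs_sigma <- vapply(dataset, function(o)
    is.null(o$data$sigma) && is.null(o$sigma), logical(1))
  if (any(needs_sigma)) {
    pilot <- .lm_multistart(dataset, scheme, init_params, free, fraction_names,
                            lower, upper, n_starts, seed, maxiter, ties)
    p_pilot <- .apply_ties(
      .theta_unpack(pilot$fit$par, free, init_params, fraction_names), ties)
    for (i in which(needs_sigma)) {
      obs <- dataset[[i]]
      r <- obs$data$signal - .obs_predict(obs, scheme, p_pilot)$pred
      tt <- obs$data$time_s
      late <- tt >= stats::quantile(tt, 0.8)
      if (sum(late) < 4) late <- rep(TRUE, length(tt))
      s <- stats::sd(r[late])
      dataset[[i]]$sigma <- max(s, 1e-12)
    }
  }

  ms <- .lm_multistart(dataset, scheme, init_params, free, fraction_names,
                       lower, upper, n_starts, seed, maxiter, ties)
  fit <- ms$fit
  params <- .apply_ties(.theta_unpack(fit$par, free, init_params, fraction_names),
                        ties)
  chi2 <- chi_squared(params, dataset, scheme)

  # zero-sensitivity screen: structurally unidentifiable parameters
  r0 <- .residual_vector(params, dataset, scheme, ties)
  unident <- character()
  for (i in seq_along(free)) {
    th <- fit$par
    h <- if (th[i] + 1e-4 <= upper[i]) 1e-4 else -1e-4  # step away from a bound
    th[i] <- th[i] + h
    r1 <- try(.residual_vector(.theta_unpack(th, free, init_params, fraction_names),
                               dataset, scheme, ties), silent = TRUE)
    if (inherits(r1, "try-error")) next
    if (sqrt(sum((r1 - r0)^2)) < 1e-10 * max(1, sqrt(sum(r0^2))))
      unident <- c(unident, free[i])
  }

  nuis <- lapply(dataset, function(obs) {
    pr <- .obs_predict(obs, scheme, params)
    list(scale = pr$scale, offset = pr$offset)
  })
  sigmas <- lapply(dataset, .obs_sigma)

  structure(list(
    params = params, free = free, chi2 = as.numeric(chi2),
    per_observation_chi2 = attr(chi2, "per_observation"),
    nuisances = nuis, sigmas = sigmas,
    converged = fit$info %in% 1:3, info = fit$info,
    message = fit$message, niter = fit$niter,
    unidentifiable = unident,
    ties = ties,
    fraction_names = fraction_names,
    scheme_name = scheme$name, bounds = NULL,
    n_residuals = length(r0), seed = seed, n_starts = n_starts),
    class = "global_fit")
}

.lm_multistart <- function(dataset, scheme, init_params, free, fraction_names,
                           lower, upper, n_starts, seed, maxiter, ties = NULL) {
  n_res <- sum(vapply(dataset, function(o) nrow(o$data), integer(1)))
  fn <- function(theta) {
    p <- .theta_unpack(theta, free, init_params, fraction_names)
    r <- try(.residual_vector(p, dataset, scheme, ties), silent = TRUE)
    # solver failure in a pathological parameter region: steer the
    # optimizer away with a large finite residual
    if (inherits(r, "try-error") || any(!is.finite(r)))
      return(rep(1e6, n_res))
    r
  }
  # documented multi-start set, truth-agnostic and log-spaced: (i) the
  # supplied initial values; (ii) all free rates at a common magnitude
  # 10^g, g in {-1, 0, 1, 2}; (iii) "split" starts with the first half of
  # the free rates at 10^g1 and the second half at 10^g2 for every ordered
  # pair g1 != g2 (covers mechanisms whose catalytic and exchange rates
  # live on different scales); fractions always start at 0.1. Seeded
  # log-uniform draws fill any remaining requested starts.
  grid <- c(-1, 0, 1, 2)
  rate_free <- setdiff(free, fraction_names)
  mk_start <- function(assign) vapply(free, function(p) {
    if (p %in% fraction_names) 0.1 else assign[[p]]
  }, numeric(1))
  starts <- list(.theta_pack(init_params, free, fraction_names))
  for (g in grid)
    starts[[length(starts) + 1]] <-
      mk_start(stats::setNames(as.list(rep(g, length(rate_free))), rate_free))
  if (length(rate_free) >= 2) {
    h1 <- rate_free[seq_len(ceiling(length(rate_free) / 2))]
    h2 <- setdiff(rate_free, h1)
    for (g1 in grid) for (g2 in grid) {
      if (g1 == g2) next
      a <- c(stats::setNames(as.list(rep(g1, length(h1))), h1),
             stats::setNames(as.list(rep(g2, length(h2))), h2))
      starts[[length(starts) + 1]] <- mk_start(a)
    }
  }
  starts <- starts[seq_len(min(length(starts), n_starts))]
  if (n_starts > length(starts)) {
    rng <- .seeded_rng(seed)
    for (s in seq_len(n_starts - length(starts))) {
      starts[[length(starts) + 1]] <- vapply(free, function(p) {
        if (p %in% fraction_names) rng$unif(0, 0.5) else rng$unif(-2, 3)
      }, numeric(1))
    }
  }
  best <- NULL
  for (th0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop_teckin("teckin_fit_failure", "all optimizer starts failed")
  list(fit = best)
}

# small self-contained uniform RNG (so generator seeds and fit seeds never
# disturb the caller's RNG stream)
.seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  nxt <- function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
  list(unif = function(a, b) a + (b - a) * nxt())
}

#' Profile-based parameter bounds at a fractional chi-square increase
#'
#' For each free parameter, finds the interval over which the re-optimized
#' chi-square (all other free parameters refit at each probe value) stays
#' below `(1 + chi2_increase)` times the fitted minimum - the FitSpace-style
#' confidence region at a 10% chi-square increase by default. Endpoints are
#' located by geometric bracketing followed by bisection to 1% relative
#' precision; profiles that never cross the threshold within a factor of
#' `max_factor` of the best fit are flagged unbounded on that side.
#'
#' @param fit a converged [fit_global()] result.
#' @param dataset,scheme the dataset and scheme used for the fit.
#' @param chi2_increase fractional chi-square increase defining the bound
#'   (default 0.10).
#' @param rel_tol relative precision of the endpoint location.
#' @param max_factor search limit as a multiplicative factor on the best-fit
#'   value.
#' @param maxiter inner refit iteration cap.
#' @return data frame with one row per free parameter: `parameter`, `lower`,
#'   `best`, `upper`, `lower_unbounded`, `upper_unbounded`. Attribute
#'   `chi2_target` records the threshold; `chi2_increase` the fraction used.
#' @export
profile_bounds <- function(fit, dataset, scheme, chi2_increase = 0.10,
                           rel_tol = 0.01, max_factor = 1000, maxiter = 100) {
  if (!inherits(fit, "global_fit") || !fit$converged)
    stop_teckin("teckin_not_converged",
                "profile_bounds requires a converged global fit")
  # fix sigmas at the values used for the fit so the objective is identical
  for (i in seq_along(dataset)) dataset[[i]]$sigma <- fit$sigmas[[i]]
  for (i in seq_along(dataset)) dataset[[i]]$data$sigma <- NULL

  target <- (1 + chi2_increase) * fit$chi2
  fraction_names <- fit$fraction_names
  out <- data.frame(parameter = fit$free,
                    lower = NA_real_, best = NA_real_, upper = NA_real_,
                    lower_unbounded = FALSE, upper_unbounded = FALSE,
                    stringsAsFactors = FALSE)

  for (j in seq_along(fit$free)) {
    p <- fit$free[j]
    v0 <- fit$params[[p]]
    out$best[j] <- v0
    if (p %in% fit$unidentifiable) {
      out$lower_unbounded[j] <- TRUE
      out$upper_unbounded[j] <- TRUE
      next
    }
    others <- setdiff(fit$free, p)
    prof <- function(v) {
      pp <- fit$params
      pp[[p]] <- v
      if (!length(others))
        return(as.numeric(chi_squared(pp, dataset, scheme, ties = fit$ties)))
      f <- fit_global(dataset, scheme, pp, free = others,
                      n_starts = 1, maxiter = maxiter, ties = fit$ties)
      f$chi2
    }
    is_frac <- p %in% fraction_names
    for (side in c("lower", "upper")) {
      step <- function(v) {
        if (is_frac) {
          if (side == "upper") v + (1 - v) * 0.5 else v * 0.5
        } else {
          if (side == "upper") v * 1.6 else v / 1.6
        }
      }
      exhausted <- function(v) {
        if (is_frac) {
          if (side == "upper") v > 1 - 1e-6 else v < 1e-6
        } else {
          if (side == "upper") v / v0 > max_factor else v0 / v > max_factor
        }
      }
      v_in <- v0; v_out <- step(v0); found <- FALSE
      repeat {
        if (prof(v_out) > target) { found <- TRUE; break }
        v_in <- v_out
        if (exhausted(v_out)) break
        v_out <- step(v_out)
      }
      if (!found) {
        out[[paste0(side, "_unbounded")]][j] <- TRUE
        out[[side]][j] <- v_out
        next
      }
      # bisection (geometric for rates, arithmetic for fractions)
      repeat {
        mid <- if (is_frac) (v_in + v_out) / 2 else sqrt(v_in * v_out)
        if (abs(v_out - v_in) <= rel_tol * max(abs(mid), 1e-300)) break
        if (prof(mid) > target) v_out <- mid else v_in <- mid
      }
      out[[side]][j] <- if (is_frac) (v_in + v_out) / 2 else sqrt(v_in * v_out)
    }
  }
  attr(out, "chi2_target") <- target
  attr(out, "chi2_increase") <- chi2_increase
  out
}

#' Equilibrium tie for the slow TEC fraction
#'
#' The resting TEC interconverts slowly and reversibly between inactive and
#' active states, so before substrate addition the two states sit at the
#' equilibrium of that step: the inactive (slow) fraction equals
#' `k_inact / (k_inact + k_rec)`. Passing this tie to [fit_global()] makes
#' the initial distribution thermodynamically consistent with the fitted
#' interconversion rates instead of treating the slow fraction as an
#' independent parameter (which is nearly degenerate with `k_inact` over a
#' finite observation window).
#'
#' @return a `ties` list suitable for [fit_global()] / [chi_squared()].
#' @export
slow_fraction_equilibrium_tie <- function() {
  list(slow_fraction = function(p)
    unname(p[["k_inact"]] / (p[["k_inact"]] + p[["k_rec"]])))
}

#' Joint fit of a bimolecular binding concentration series
#'
#' Fits the association and dissociation rate constants of the one-step
#' reversible binding scheme to stopped-flow traces collected at several
#' post-mix ligand concentrations, with explicit ligand depletion and
#' per-trace fluorescence scale/offset nuisances. The equilibrium
#' dissociation constant is derived as `Kd = k_minus1 / k_plus1`.
#'
#' @param traces list of trace data frames (`time_s`, `signal`, optional
#'   `sigma`), each carrying attributes `ligand_total_M` and
#'   `receptor_total_M` (as produced by [generate_binding_series()]), or a
#'   ready-made [kinetic_dataset()].
#' @param scheme binding scheme, default [build_bimolecular_binding_scheme()].
#' @param init_params starting values for `k_plus1` (per molar per second)
#'   and `k_minus1` (per second).
#' @param ... passed to [fit_global()].
#' @return a `global_fit` with an additional `Kd` field (molar).
#' @export
fit_binding_series <- function(traces,
                               scheme = build_bimolecular_binding_scheme(),
                               init_params = c(k_plus1 = 1e6, k_minus1 = 1),
                               ...) {
  if (inherits(traces, "kinetic_dataset")) {
    dataset <- traces
    ligs <- vapply(dataset, function(o) o$conditions$species_totals[["ligand"]],
                   numeric(1))
  } else {
    ligs <- vapply(traces, function(tr) attr(tr, "ligand_total_M"), numeric(1))
    obs <- lapply(traces, function(tr) {
      kin_observation(
        data = tr,
        observable = observable_map("fluorescence",
                                    coefficients = c(TEC_bound = 1)),
        conditions = list(receptor_total = attr(tr, "receptor_total_M"),
                          species_totals = c(ligand = attr(tr, "ligand_total_M")),
                          dead_time = attr(tr, "dead_time_s") %||% 0))
    })
    dataset <- kinetic_dataset(obs)
  }
  if (length(unique(signif(ligs, 10))) < 3)
    stop_teckin("teckin_single_concentration",
                paste0("binding fit needs >= 3 distinct ligand concentrations ",
                       "(k_plus1 and k_minus1 are not separable otherwise)"))
  fit <- fit_global(dataset, scheme, init_params,
                    free = c("k_plus1", "k_minus1"), ...)
  fit$Kd <- unname(fit$params[["k_minus1"]] / fit$params[["k_plus1"]])
  fit
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Global fit (scheme '", x$scheme_name, "'): chi2 = ",
      format(x$chi2, digits = 6), ", converged = ", x$converged,
      ", iterations = ", x$niter, "\n", sep = "")
  for (p in x$free)
    cat(sprintf("  %-14s %.6g\n", p, x$params[[p]]))
  if (!is.null(x$Kd))
    cat(sprintf("  Kd = %.4g M\n", x$Kd))
  if (length(x$unidentifiable))
    cat("  [flag] zero-sensitivity parameter(s): ",
        paste(x$unidentifiable, collapse = ", "), "\n", sep = "")
  if (!is.null(x$bounds)) {
    cat("  Profile bounds (chi2 +", attr(x$bounds, "chi2_increase") * 100, "%):\n")
    print(x$bounds, row.names = FALSE)
  }
  invisible(x)
}
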