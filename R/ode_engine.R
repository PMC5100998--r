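#' Integrate a kinetic scheme over time
#'
#' Numerically integrates the mass-action rate equations of a
#' [kinetic_scheme()] with a stiff-capable solver (`deSolve::ode`, method
#' `lsoda`, rtol 1e-8, atol 1e-10; rate constants within one fit can span
#' more than three orders of magnitude). Schemes with concentration-multiplied
#' transitions are integrated in concentration space (depletion coupling is
#' nonlinear in fractions) and converted back to fractions on output.
#'
#' @param scheme a `kinetic_scheme`.
#' @param params named numeric vector covering every name in
#'   [rate_parameters()]: per-second for unimolecular steps, per molar per
#'   second for concentration-multiplied steps, dimensionless in `[0,1]` for
#'   initial-fraction parameters.
#' @param times strictly increasing non-negative times in seconds.
#' @param conditions list of experimental conditions; required for schemes
#'   with tracked species: `receptor_total` (molar) and `species_totals`
#'   (named molar vector, one entry per tracked species).
#' @return an object of class `trajectory`: `times`, `state_fractions`
#'   (time x state matrix, rows summing to 1), and `species_concentrations`
#'   (named list of free-concentration series, molar).
#' @export
simulate_scheme <- function(scheme, params, times, conditions = list()) {
  if (length(times) < 1 || any(diff(times) <= 0))
    stop_teckin("teckin_bad_times", "`times` must be strictly increasing")
  if (times[1] < 0)
    stop_teckin("teckin_bad_times", "`times` must be non-negative")
  needed <- rate_parameters(scheme)
  missing <- setdiff(needed, names(params))
  # initial-fraction parameters may be omitted: the scheme default is used
  missing_rates <- intersect(missing, scheme$transitions$rate)
  if (length(missing_rates))
    stop_teckin("teckin_missing_rate",
                paste0("missing rate parameter(s): ",
                       paste(missing_rates, collapse = ", ")))
  rates <- params[scheme$transitions$rate]
  if (any(rates < 0))
    stop_teckin("teckin_negative_rate",
                paste0("negative rate parameter(s): ",
                       paste(scheme$transitions$rate[rates < 0], collapse = ", ")))

  init <- .initial_fractions(scheme, params)
  n <- length(scheme$states)
  tr <- scheme$transitions
  from_i <- match(tr$from, scheme$states)
  to_i <- match(tr$to, scheme$states)
  kvec <- unname(params[tr$rate])
  has_species <- any(!is.na(tr$species))

  if (has_species) {
    R0 <- conditions$receptor_total
    totals <- conditions$species_totals
    sp_used <- unique(stats::na.omit(tr$species))
    if (is.null(R0) || is.null(totals) || !all(sp_used %in% names(totals)))
      stop_teckin("teckin_missing_condition",
                  paste0("scheme tracks species (",
                         paste(sp_used, collapse = ", "),
                         "); `conditions` must supply `receptor_total` and ",
                         "`species_totals` for each"))
    stoich <- matrix(0, nrow = length(sp_used), ncol = n,
                     dimnames = list(sp_used, scheme$states))
    for (sp in sp_used) {
      v <- scheme$species_stoichiometry[[sp]] %||% numeric()
      stoich[sp, names(v)] <- v
    }
    y0 <- init * R0
    derivs <- function(t, y, p) {
      free <- totals[sp_used] - as.vector(stoich %*% y)
      eff <- kvec * y[from_i]
      isp <- !is.na(tr$species)
      eff[isp] <- eff[isp] * pmax(free[match(tr$species[isp], sp_used)], 0)
      dy <- numeric(n)
      for (j in seq_along(eff)) {
        dy[from_i[j]] <- dy[from_i[j]] - eff[j]
        dy[to_i[j]] <- dy[to_i[j]] + eff[j]
      }
      list(dy)
    }
  } else {
    y0 <- init
    # constant rate matrix: dX/dt = A %*% X
    A <- matrix(0, n, n)
    for (j in seq_len(nrow(tr))) {
      A[from_i[j], from_i[j]] <- A[from_i[j], from_i[j]] - kvec[j]
      A[to_i[j], from_i[j]] <- A[to_i[j], from_i[j]] + kvec[j]
    }
    derivs <- function(t, y, p) list(as.vector(A %*% y))
  }

  t_out <- times
  prepend0 <- times[1] > 0
  if (prepend0) t_out <- c(0, times)
  # absolute tolerance is scale-aware: concentration-space integration uses
  # 1e-12 of the receptor pool so fraction-level error stays below the
  # negative-fraction clamp
  atol <- if (has_species) 1e-12 * conditions$receptor_total else 1e-10
  sol <- deSolve::ode(y = y0, times = t_out, func = derivs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = atol)
  if (nrow(sol) < length(t_out)) {
    t_fail <- t_out[nrow(sol) + 1]
    stop_teckin("teckin_solver_failure",
                paste0("ODE solver failed to reach t = ", format(t_fail), " s"))
  }
  y <- sol[, -1, drop = FALSE]
  if (prepend0) y <- y[-1, , drop = FALSE]
  colnames(y) <- scheme$states

  frac <- if (has_species) y / conditions$receptor_total else y
  if (any(frac < -1e-10))
    stop_teckin("teckin_negative_fraction",
                paste0("state fraction below -1e-10 at t = ",
                       format(times[which(rowSums(frac < -1e-10) > 0)[1]]), " s"))
  frac[frac < 0] <- 0  # clamp solver noise in [-1e-10, 0)

  species_conc <- list()
  if (has_species) {
    for (sp in unique(stats::na.omit(tr$species))) {
      bound <- as.vector(y %*% (stoich[sp, ]))
      species_conc[[sp]] <- unname(conditions$species_totals[[sp]] - bound)
    }
  }
  structure(list(times = times, state_fractions = frac,
                 species_concentrations = species_conc,
                 conditions = conditions),
            class = "trajectory")
}

# Rebind the initial distribution from the parameter set: states named in
# `initial_params` take their fraction from the parameter; remaining mass is
# shared among the other states in proportion to their default weights.
.initial_fractions <- function(scheme, params) {
  init <- scheme$initial
  ip <- scheme$initial_params
  if (is.null(ip)) return(init)
  avail <- ip[unname(ip) %in% names(params)]
  if (!length(avail)) return(init)
  vals <- params[unname(avail)]
  if (any(vals < 0 | vals > 1))
    stop_teckin("teckin_bad_fraction",
                "initial-fraction parameters must lie in [0, 1]")
  out <- init
  out[names(avail)] <- vals
  rest <- setdiff(scheme$states, names(avail))
  w <- init[rest]
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(rest), length(rest))
  out[rest] <- (1 - sum(vals)) * w
  out
}

#' Project a trajectory onto an observable signal
#'
#' @param traj a `trajectory` from [simulate_scheme()].
#' @param obs an [observable_map()]. For `state_sum` the result is the summed
#'   fraction of the product states (in `[0,1]`); for `fluorescence` it is
#'   `offset + scale * sum(coefficients * fractions)`.
#' @return numeric signal series, one value per trajectory time.
#' @export
project_observable <- function(traj, obs) {
  frac <- traj$state_fractions
  st <- if (obs$kind == "state_sum") obs$states else names(obs$coefficients)
  unknown <- setdiff(st, colnames(frac))
  if (length(unknown))
    stop_teckin("teckin_unknown_state",
                paste0("observable references unknown state(s): ",
                       paste(unknown, collapse = ", ")))
  if (obs$kind == "state_sum") {
    rowSums(frac[, obs$states, drop = FALSE])
  } else {
    base <- as.vector(frac[, names(obs$coefficients), drop = FALSE] %*%
                        obs$coefficients)
    obs$offset + obs$scale * base
  }
}

#' Tidy data frame view of a trajectory
#'
#' @param x a `trajectory`.
#' @param ... unused.
#' @return data frame with columns `time_s`, `state`, `fraction` (long
#'   format, suitable for CSV export).
#' @export
as.data.frame.trajectory <- function(x, ...) {
  frac <- x$state_fractions
  data.frame(time_s = rep(x$times, times = ncol(frac)),
             state = rep(colnames(frac), each = length(x$times)),
             fraction = as.vector(frac),
             stringsAsFactors = FALSE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$times), " times in [",
      format(min(x$times)), ", ", format(max(x$times)), "] s, states: ",
      paste(colnames(x$state_fractions), collapse = ", "), "\n", sep = "")
  invisible(x)
}
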