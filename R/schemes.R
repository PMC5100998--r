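#' Construct a mass-action kinetic scheme
#'
#' A kinetic scheme is a set of named states connected by first-order
#' transitions. A transition may optionally be multiplied by the free
#' concentration of a tracked species (e.g. a ligand), which turns it into an
#' effective bimolecular step with explicit depletion bookkeeping.
#'
#' @param name short identifier for the scheme.
#' @param states character vector of unique state names.
#' @param transitions data frame with columns `from`, `to`, `rate`
#'   (rate-parameter name) and optionally `species` (name of the concentration
#'   species multiplying the rate; `NA` for unimolecular steps).
#' @param initial named numeric vector of initial state fractions (must sum
#'   to 1).
#' @param initial_params optional named character vector mapping a state name
#'   to a rate-parameter name; at simulation time that state's initial
#'   fraction is taken from the parameter set (e.g. the slow TEC fraction)
#'   and the remaining mass is distributed over the other states in
#'   proportion to their default initial weights.
#' @param species_stoichiometry optional named list: for each tracked species,
#'   a named numeric vector giving how many molecules of that species are
#'   sequestered per receptor in each state (states not listed bind none).
#'
#' @return an object of class `kinetic_scheme`.
#' @seealso [build_three_step_scheme()], [build_bimolecular_binding_scheme()],
#'   [build_backtrack_cleavage_scheme()], [validate_scheme()]
#' @export
kinetic_scheme <- function(name, states, transitions, initial,
                           initial_params = NULL,
                           species_stoichiometry = NULL) {
  if (is.null(transitions$species)) transitions$species <- NA_character_
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  initial <- initial[states[states %in% names(initial)]]
  missing_init <- setdiff(states, names(initial))
  if (length(missing_init)) {
    add <- stats::setNames(rep(0, length(missing_init)), missing_init)
    initial <- c(initial, add)[states]
  }
  scheme <- structure(
    list(name = name, states = states, transitions = transitions,
         initial = initial, initial_params = initial_params,
         species_stoichiometry = species_stoichiometry),
    class = "kinetic_scheme")
  findings <- validate_scheme(scheme)
  if (length(findings))
    stop_teckin("teckin_invalid_scheme",
                paste0("invalid kinetic scheme '", name, "': ",
                       paste(findings, collapse = "; ")))
  scheme
}

#' Validate a kinetic scheme
#'
#' Checks the structural invariants of a [kinetic_scheme()]: unique state
#' names, transitions referencing declared states, initial fractions summing
#' to one (within 1e-12), non-negative initial fractions, at least one
#' rate-parameter name, and species stoichiometries referencing declared
#' states.
#'
#' @param scheme a `kinetic_scheme` (or a bare list with the same fields).
#' @return character vector of findings; empty when all invariants hold.
#' @export
validate_scheme <- function(scheme) {
  findings <- character()
  st <- scheme$states
  if (anyDuplicated(st))
    findings <- c(findings, paste0("duplicate state name(s): ",
                                   paste(unique(st[duplicated(st)]), collapse = ", ")))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    for (col in c("from", "to")) {
      s <- tr[[col]][i]
      if (!s %in% st)
        findings <- c(findings, paste0("transition ", i, " references undeclared state '",
                                       s, "'"))
    }
  }
  if (nrow(tr) == 0 || !length(stats::na.omit(unique(tr$rate))))
    findings <- c(findings, "scheme declares no rate parameters")
  init <- scheme$initial
  bad <- setdiff(names(init), st)
  if (length(bad))
    findings <- c(findings, paste0("initial distribution references undeclared state(s): ",
                                   paste(bad, collapse = ", ")))
  if (any(init < 0))
    findings <- c(findings, "initial fractions must be non-negative")
  if (abs(sum(init) - 1) > 1e-12)
    findings <- c(findings, paste0("initial fractions sum to ", format(sum(init)),
                                   ", not 1 (normalization violated)"))
  if (!is.null(scheme$initial_params)) {
    bad <- setdiff(names(scheme$initial_params), st)
    if (length(bad))
      findings <- c(findings, paste0("initial_params references undeclared state(s): ",
                                     paste(bad, collapse = ", ")))
  }
  for (sp in names(scheme$species_stoichiometry %||% list())) {
    bad <- setdiff(names(scheme$species_stoichiometry[[sp]]), st)
    if (length(bad))
      findings <- c(findings, paste0("stoichiometry of species '", sp,
                                     "' references undeclared state(s): ",
                                     paste(bad, collapse = ", ")))
  }
  findings
}

#' Rate-parameter names of a scheme
#'
#' All names the parameter set must provide at simulation time: the
#' transition rate constants plus any initial-distribution parameters (such
#' as the slow TEC fraction).
#'
#' @param scheme a `kinetic_scheme`.
#' @return character vector of parameter names.
#' @export
rate_parameters <- function(scheme) {
  unique(c(scheme$transitions$rate, unname(scheme$initial_params)))
}

#' Three-step nucleotide addition / translocation scheme
#'
#' The mechanism used to analyse combined quench-flow nucleotide-incorporation
#' and stopped-flow translocation data: the initial TEC16 slowly and
#' reversibly interconverts between an inactive and an active state
#' (`k_rec`, `k_inact`); the active TEC16 undergoes irreversible nucleotide
#' addition to the pre-translocated TEC17 (`k_add`, pseudo-first-order at
#' saturating NTP) followed by irreversible forward translocation (`k_tr`).
#'
#' @param slow_fraction default initial inactive fraction in (0, 1); the
#'   fraction is re-bound from the parameter set (name `slow_fraction`) at
#'   simulation/fit time when supplied there.
#' @return a `kinetic_scheme` with states `TEC16_inactive`, `TEC16_active`,
#'   `TEC17_pre`, `TEC17_post`.
#' @export
build_three_step_scheme <- function(slow_fraction = 0.08) {
  stopifnot(slow_fraction >= 0, slow_fraction <= 1)
  kinetic_scheme(
    name = "three_step",
    states = c("TEC16_inactive", "TEC16_active", "TEC17_pre", "TEC17_post"),
    transitions = data.frame(
      from = c("TEC16_inactive", "TEC16_active", "TEC16_active", "TEC17_pre"),
      to   = c("TEC16_active", "TEC16_inactive", "TEC17_pre", "TEC17_post"),
      rate = c("k_rec", "k_inact", "k_add", "k_tr"),
      stringsAsFactors = FALSE),
    initial = c(TEC16_inactive = slow_fraction,
                TEC16_active = 1 - slow_fraction,
                TEC17_pre = 0, TEC17_post = 0),
    initial_params = c(TEC16_inactive = "slow_fraction"))
}

#' One-step reversible ligand-binding scheme with explicit depletion
#'
#' Bimolecular association of a ligand (e.g. NusG) with the TEC,
#' `TEC_free + L -> TEC_bound` at `k_plus1` (per molar per second) times the
#' free-ligand concentration, and dissociation `TEC_bound -> TEC_free` at
#' `k_minus1` (per second). The ligand is tracked as a conserved species:
#' free = total - bound, so the scheme is valid in the depletion regime where
#' ligand and receptor concentrations are comparable.
#'
#' @return a `kinetic_scheme` with states `TEC_free`, `TEC_bound` and a
#'   tracked species `ligand`.
#' @export
build_bimolecular_binding_scheme <- function() {
  kinetic_scheme(
    name = "bimolecular_binding",
    states = c("TEC_free", "TEC_bound"),
    transitions = data.frame(
      from = c("TEC_free", "TEC_bound"),
      to = c("TEC_bound", "TEC_free"),
      rate = c("k_plus1", "k_minus1"),
      species = c("ligand", NA_character_),
      stringsAsFactors = FALSE),
    initial = c(TEC_free = 1, TEC_bound = 0),
    species_stoichiometry = list(ligand = c(TEC_bound = 1)))
}

#' Backtracking-limited RNA cleavage scheme
#'
#' Emulates cleavage-factor-assisted RNA cleavage limited by the rate of
#' polymerase backtracking: `TEC_pre -> TEC_backtracked` at `k_bt`, return
#' `TEC_backtracked -> TEC_pre` at `k_fwd`, and irreversible cleavage
#' `TEC_backtracked -> TEC_cleaved` at `k_cleave`. When `k_cleave >> k_bt`
#' and `k_fwd` is small, the cleaved fraction accumulates as a
#' single-exponential with observed rate approximately `k_bt`, which is how
#' the cleavage assays report backtracking.
#'
#' @return a `kinetic_scheme` with states `TEC_pre`, `TEC_backtracked`,
#'   `TEC_cleaved`.
#' @export
build_backtrack_cleavage_scheme <- function() {
  kinetic_scheme(
    name = "backtrack_cleavage",
    states = c("TEC_pre", "TEC_backtracked", "TEC_cleaved"),
    transitions = data.frame(
      from = c("TEC_pre", "TEC_backtracked", "TEC_backtracked"),
      to   = c("TEC_backtracked", "TEC_pre", "TEC_cleaved"),
      rate = c("k_bt", "k_fwd", "k_cleave"),
      stringsAsFactors = FALSE),
    initial = c(TEC_pre = 1, TEC_backtracked = 0, TEC_cleaved = 0))
}

.scheme_registry <- function(name) {
  switch(name,
         three_step = build_three_step_scheme(),
         bimolecular_binding = build_bimolecular_binding_scheme(),
         backtrack_cleavage = build_backtrack_cleavage_scheme(),
         stop_teckin("teckin_unknown_scheme",
                     paste0("unknown scheme name '", name, "'")))
}

#' Map a state trajectory onto an experimental observable
#'
#' Two kinds of read-out are supported. `state_sum` sums the fractions of a
#' set of states (gel product fraction). `fluorescence` computes
#' `offset + scale * sum(coefficient_s * fraction_s)` with per-state signal
#' coefficients; the sign of the coefficients carries the direction of the
#' fluorescence change (rising 2-AP vs falling 6-MI), and `scale`/`offset`
#' are the per-trace nuisance parameters profiled during fitting.
#'
#' @param kind `"state_sum"` or `"fluorescence"`.
#' @param states for `state_sum`: character vector of states counted as
#'   product.
#' @param coefficients for `fluorescence`: named numeric vector of per-state
#'   signal coefficients.
#' @param scale,offset trace-level nuisance parameters; `scale` must be
#'   strictly positive.
#' @return an object of class `observable_map`.
#' @export
observable_map <- function(kind = c("state_sum", "fluorescence"),
                           states = NULL, coefficients = NULL,
                           scale = 1, offset = 0) {
  kind <- match.arg(kind)
  if (kind == "state_sum" && is.null(states))
    stop_teckin("teckin_invalid_observable", "state_sum observable needs `states`")
  if (kind == "fluorescence" && is.null(coefficients))
    stop_teckin("teckin_invalid_observable", "fluorescence observable needs `coefficients`")
  if (scale <= 0)
    stop_teckin("teckin_invalid_observable", "observable scale must be strictly positive")
  structure(list(kind = kind, states = states, coefficients = coefficients,
                 scale = scale, offset = offset),
            class = "observable_map")
}

#' Serialize a kinetic scheme to JSON
#'
#' @param scheme a `kinetic_scheme`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  doc <- list(name = scheme$name, states = scheme$states,
              transitions = scheme$transitions,
              initial_distribution = as.list(scheme$initial),
              initial_params = as.list(scheme$initial_params %||% list()),
              species_stoichiometry = lapply(scheme$species_stoichiometry %||% list(),
                                             as.list))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Deserialize a kinetic scheme from JSON
#'
#' @param x a JSON string or a path to a JSON file produced by
#'   [scheme_to_json()].
#' @return a `kinetic_scheme`.
#' @export
scheme_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  ip <- doc$initial_params
  ip <- if (length(ip)) unlist(ip) else NULL
  ss <- doc$species_stoichiometry
  ss <- if (length(ss)) lapply(ss, unlist) else NULL
  kinetic_scheme(name = doc$name, states = doc$states,
                 transitions = doc$transitions,
                 initial = unlist(doc$initial_distribution),
                 initial_params = ip, species_stoichiometry = ss)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", length(x$states), " states, ",
      nrow(x$transitions), " transitions\n", sep = "")
  for (i in seq_len(nrow(x$transitions))) {
    tr <- x$transitions[i, ]
    sp <- if (!is.na(tr$species)) paste0(" * [", tr$species, "]") else ""
    cat("  ", tr$from, " -> ", tr$to, "  (", tr$rate, sp, ")\n", sep = "")
  }
  invisible(x)
}
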