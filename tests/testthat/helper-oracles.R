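# Independent oracles used to cross-check the implementation.

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

# rate matrix A of a unimolecular scheme: dX/dt = A X
rate_matrix <- function(scheme, params) {
  n <- length(scheme$states)
  A <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    k <- params[[tr$rate[i]]]
    A[tr$from[i], tr$from[i]] <- A[tr$from[i], tr$from[i]] - k
    A[tr$to[i], tr$from[i]] <- A[tr$to[i], tr$from[i]] + k
  }
  A
}

# matrix-exponential solution, independent of the ODE integrator
expm_solution <- function(scheme, params, times, init = NULL) {
  A <- rate_matrix(scheme, params)
  if (is.null(init)) {
    init <- scheme$initial
    ip <- scheme$initial_params
    if (!is.null(ip)) {
      for (st in names(ip))
        if (ip[[st]] %in% names(params)) {
          init[st] <- params[[ip[[st]]]]
          rest <- setdiff(scheme$states, names(ip))
          w <- scheme$initial[rest]
          w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(rest), length(rest))
          init[rest] <- (1 - sum(init[names(ip)])) * w
        }
    }
  }
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(A * t) %*% init), numeric(length(scheme$states))))
}

# random linear-chain scheme with extra random back-edges
random_unimolecular_scheme <- function(n_states, extra_edges = 1) {
  states <- paste0("S", seq_len(n_states))
  from <- states[-n_states]; to <- states[-1]
  if (extra_edges > 0) {
    i <- sample(2:n_states, extra_edges)
    from <- c(from, states[i]); to <- c(to, states[i - 1])
  }
  rates <- paste0("k", seq_along(from))
  init <- runif(n_states); init <- init / sum(init)
  # exact normalization to survive the 1e-12 invariant check
  init[n_states] <- 1 - sum(init[-n_states])
  kinetic_scheme("random_chain", states,
                 data.frame(from = from, to = to, rate = rates,
                            stringsAsFactors = FALSE),
                 initial = stats::setNames(init, states))
}

# brute-force equilibrium complex concentration: bisection on the mass
# balance (R - C)(L - C) = Kd * C, monotone on [0, min(R, L)]
brute_force_bound_fraction <- function(kd, R, L) {
  if (L == 0) return(0)
  f <- function(C) (R - C) * (L - C) - kd * C
  lo <- 0; hi <- min(R, L)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / R
}

# reference three-step parameter set (nucleotide addition / translocation /
# inactive-state exchange), with the slow fraction at the equilibrium of
# the inactivation step
three_step_truth <- function() {
  p <- c(k_add = 28, k_tr = 65, k_rec = 1.1, k_inact = 0.09)
  p["slow_fraction"] <- p[["k_inact"]] / (p[["k_inact"]] + p[["k_rec"]])
  p
}

neutral_three_step_init <- function() {
  c(k_add = 10, k_tr = 10, k_rec = 1, k_inact = 0.1, slow_fraction = 0.1)
}
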