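# small noiseless product-fraction dataset used by several blocks
noiseless_three_step_obs <- function(times = logspace(0.004, 10, 12)) {
  sch <- build_three_step_scheme()
  traj <- simulate_scheme(sch, three_step_truth(), times)
  obsmap <- observable_map("state_sum", states = c("TEC17_pre", "TEC17_post"))
  kin_observation(data.frame(time_s = times,
                             signal = project_observable(traj, obsmap),
                             sigma = 0.02),
                  obsmap)
}

test_that("chi-square follows its definition", {
  sch <- build_three_step_scheme()
  ds <- kinetic_dataset(list(noiseless_three_step_obs()))
  expect_equal(as.numeric(chi_squared(three_step_truth(), ds, sch)), 0,
               tolerance = 1e-12)

  # single point, residual 2, variance 1 -> 4; doubling residuals quadruples
  obs <- noiseless_three_step_obs(times = 1)
  p1 <- obs$data$signal
  mk <- function(r) kinetic_dataset(list(
    kin_observation(data.frame(time_s = 1, signal = p1 + r, sigma = 1),
                    obs$observable)))
  expect_equal(as.numeric(chi_squared(three_step_truth(), mk(2), sch)), 4,
               tolerance = 1e-9)
  expect_equal(as.numeric(chi_squared(three_step_truth(), mk(4), sch)), 16,
               tolerance = 1e-9)
  bad <- kinetic_dataset(list(
    kin_observation(data.frame(time_s = 1, signal = 1, sigma = 0),
                    obs$observable)))
  expect_error(chi_squared(three_step_truth(), bad, sch),
               class = "teckin_nonpositive_variance")
})

test_that("fitting noiseless data from the truth is a fixed point", {
  sch <- build_three_step_scheme()
  ds <- kinetic_dataset(list(noiseless_three_step_obs()))
  fit <- fit_global(ds, sch, three_step_truth(), n_starts = 1)
  expect_true(fit$converged)
  expect_lt(fit$chi2, 1e-10)
  expect_equal(fit$params[["k_add"]], 28, tolerance = 1e-4)
  expect_equal(fit$params[["k_tr"]], 65, tolerance = 1e-3)
})

test_that("chi-square and fits are invariant to observation order", {
  sch <- build_three_step_scheme()
  ds <- generate_three_step_dataset(three_step_truth(), seed = 9,
                                    n_qf = 1, n_sf = 1, sf_n = 80)
  ds_rev <- kinetic_dataset(rev(unclass(ds)))
  init <- neutral_three_step_init()
  expect_equal(as.numeric(chi_squared(init, ds, sch)),
               as.numeric(chi_squared(init, ds_rev, sch)), tolerance = 1e-12)
  # a well-identified two-parameter fit converges to the same optimum from
  # either ordering
  init2 <- three_step_truth(); init2[["k_add"]] <- 20; init2[["k_tr"]] <- 40
  f1 <- fit_global(ds, sch, init2, free = c("k_add", "k_tr"), n_starts = 1)
  f2 <- fit_global(ds_rev, sch, init2, free = c("k_add", "k_tr"), n_starts = 1)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-8)
  expect_equal(f1$params, f2$params, tolerance = 1e-3)
})

test_that("profile bounds match the closed-form chi-square parabola", {
  # near-linear regime: y = k * t to within 0.05%, so chi2(k) is an
  # analytic parabola with halfwidth sqrt(0.1 chi2_min / sum(t^2/sigma^2))
  sch <- kinetic_scheme("ab", c("A", "B"),
                        data.frame(from = "A", to = "B", rate = "k"),
                        initial = c(A = 1, B = 0))
  k0 <- 1e-3
  t <- seq(0.1, 1, length.out = 20)
  sigma <- 2e-4
  set.seed(31)
  y <- k0 * t + rnorm(20, 0, sigma)
  obsmap <- observable_map("state_sum", states = "B")
  ds <- kinetic_dataset(list(
    kin_observation(data.frame(time_s = t, signal = y, sigma = sigma), obsmap)))
  fit <- fit_global(ds, sch, c(k = 5e-4), n_starts = 1)
  b <- profile_bounds(fit, ds, sch, rel_tol = 1e-3)
  k_hat <- fit$params[["k"]]
  halfwidth <- sqrt(0.1 * fit$chi2 / sum(t^2 / sigma^2))
  expect_equal(b$lower, k_hat - halfwidth, tolerance = 0.02 * halfwidth / k_hat)
  expect_equal(b$upper, k_hat + halfwidth, tolerance = 0.02 * halfwidth / k_hat)
  # bounds contain the best fit; endpoint chi2 equals the target within 1%
  expect_true(b$lower <= b$best && b$best <= b$upper)
  pp <- fit$params; pp[["k"]] <- b$upper
  expect_equal(as.numeric(chi_squared(pp, ds, sch)), 1.1 * fit$chi2,
               tolerance = 0.01)
})

test_that("zero-sensitivity parameters are flagged and profile unbounded", {
  sch <- kinetic_scheme("abc", c("A", "B", "C"),
                        data.frame(from = c("A", "C"), to = c("B", "A"),
                                   rate = c("k1", "k_dead")),
                        initial = c(A = 1, B = 0, C = 0))
  t <- seq(0.1, 2, length.out = 12)
  y <- 1 - exp(-0.8 * t)
  ds <- kinetic_dataset(list(kin_observation(
    data.frame(time_s = t, signal = y, sigma = 0.01),
    observable_map("state_sum", states = "B"))))
  fit <- fit_global(ds, sch, c(k1 = 0.5, k_dead = 1), n_starts = 1)
  expect_true("k_dead" %in% fit$unidentifiable)
  b <- profile_bounds(fit, ds, sch)
  row <- b[b$parameter == "k_dead", ]
  expect_true(row$lower_unbounded && row$upper_unbounded)
  # profiling a non-converged fit is refused
  broken <- fit; broken$converged <- FALSE
  expect_error(profile_bounds(broken, ds, sch),
               class = "teckin_not_converged")
})

test_that("dual-observable fits recover the three-step rate constants", {
  # 20 seeded replicates of the quench-flow + stopped-flow design; the
  # median estimate of each rate lies inside its reference profile interval
  sch <- build_three_step_scheme()
  truth <- three_step_truth()
  init <- neutral_three_step_init()
  est <- matrix(NA_real_, 20, 4,
                dimnames = list(NULL, c("k_add", "k_tr", "k_rec", "k_inact")))
  for (r in 1:20) {
    ds <- generate_three_step_dataset(truth, seed = 5000 + r)
    fit <- fit_global(ds, sch, init, n_starts = 5, seed = 1,
                      ties = slow_fraction_equilibrium_tie())
    est[r, ] <- unlist(fit$params[colnames(est)])
  }
  ref <- list(k_add = c(27, 30), k_tr = c(60, 73),
              k_rec = c(0.4, 2.7), k_inact = c(0.03, 0.3))
  for (p in colnames(est)) {
    m <- median(est[, p])
    expect_gte(m, ref[[p]][1])
    expect_lte(m, ref[[p]][2])
  }
})

test_that("binding series fits recover both rate constants and the Kd", {
  spec <- generator_spec("bimolecular_binding",
                         c(k_plus1 = 9.2e6, k_minus1 = 1.1),
                         "binding_series", seed = 3,
                         design = list(n_points = 200))
  traces <- generate_binding_series(spec, c(0.2, 1, 4, 20) * 1e-6)
  fit <- fit_binding_series(traces, n_starts = 5, seed = 4)
  expect_true(fit$converged)
  expect_equal(fit$params[["k_plus1"]], 9.2e6, tolerance = 0.10)
  expect_equal(fit$params[["k_minus1"]], 1.1, tolerance = 0.10)
  expect_equal(fit$Kd * 1e6, 0.12, tolerance = 0.10)
})

test_that("single-concentration binding input is rejected as non-separable", {
  spec <- generator_spec("bimolecular_binding",
                         c(k_plus1 = 9.2e6, k_minus1 = 1.1),
                         "binding_series", seed = 3,
                         design = list(n_points = 50))
  traces <- generate_binding_series(spec, 2e-6)
  expect_error(fit_binding_series(traces),
               class = "teckin_single_concentration")
})

test_that("high-ligand relaxation approaches the pseudo-first-order rate", {
  # at 10 uM post-mix ligand the observed rate is ~ k_plus1 * L + k_minus1
  spec <- generator_spec("bimolecular_binding",
                         c(k_plus1 = 9.2e6, k_minus1 = 1.1),
                         "binding_series", seed = 8, noise = 0,
                         design = list(t_max = 0.2, n_points = 300))
  tr <- generate_binding_series(spec, 20e-6)[[1]]
  f <- fit_stretched_exponential(tr, beta_starts = 1)
  expect_equal(1 / f$tau, 9.2e6 * 10e-6 + 1.1, tolerance = 0.05)
})
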