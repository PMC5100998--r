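test_that("generators are bit-reproducible per seed", {
  spec <- generator_spec("three_step", three_step_truth(), "quench_flow",
                         seed = 77)
  expect_identical(generate_quench_flow(spec), generate_quench_flow(spec))
  sf <- generator_spec("backtrack_cleavage",
                       c(k_bt = 0.5, k_fwd = 0, k_cleave = 50),
                       "stopped_flow", seed = 78)
  expect_identical(generate_stopped_flow_trace(sf),
                   generate_stopped_flow_trace(sf))
  other <- sf; other$seed <- 79L
  expect_false(identical(generate_stopped_flow_trace(sf)$signal,
                         generate_stopped_flow_trace(other)$signal))
  tit <- generator_spec(assay = "titration", params = c(Kd = 0.12e-6),
                        seed = 80)
  lv <- seq(0, 1e-6, length.out = 8)
  expect_identical(generate_titration(tit, lv)$signal,
                   generate_titration(tit, lv)$signal)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_quench_flow(
    generator_spec("three_step", three_step_truth(), "quench_flow", seed = 1)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("zero-noise generators lie exactly on the model", {
  spec <- generator_spec("three_step", three_step_truth(), "quench_flow",
                         noise = 0, seed = 1)
  qf <- generate_quench_flow(spec)
  traj <- simulate_scheme(build_three_step_scheme(), three_step_truth(),
                          qf$time_s)
  clean <- project_observable(traj, observable_map(
    "state_sum", states = c("TEC17_pre", "TEC17_post")))
  expect_equal(qf$signal, clean, tolerance = 1e-12)
  expect_equal(range(qf$time_s), c(0.004, 10), tolerance = 1e-12)
  expect_equal(nrow(qf), 12)

  lv <- seq(0, 1e-6, length.out = 8)
  tit <- generate_titration(generator_spec(assay = "titration",
                                           params = c(Kd = 0.12e-6),
                                           noise = 0, seed = 1), lv)
  cu <- titration_curve(lv, rep(0, 8), 1e-7)
  expect_equal(tit$signal, titration_model(cu, 0.12e-6, 1, 0.5),
               tolerance = 1e-12)
  # zero-ligand anchor sits at the free-state signal
  expect_equal(tit$signal[1], 1, tolerance = 1e-12)
})

test_that("stopped-flow traces respect the dead time", {
  spec <- generator_spec("backtrack_cleavage",
                         c(k_bt = 0.5, k_fwd = 0, k_cleave = 50),
                         "stopped_flow", seed = 2)
  tr <- generate_stopped_flow_trace(spec)
  expect_gte(min(tr$time_s), 0.0015)
  expect_equal(attr(tr, "dead_time_s"), 0.0015)
})

test_that("generated noise has the specified standard deviation", {
  spec0 <- generator_spec("three_step", three_step_truth(), "quench_flow",
                          noise = 0, seed = 1, design = list(n_points = 5))
  clean <- generate_quench_flow(spec0)$signal
  draws <- vapply(1:500, function(i) {
    sp <- generator_spec("three_step", three_step_truth(), "quench_flow",
                         noise = 0.02, seed = i, design = list(n_points = 5))
    generate_quench_flow(sp)$signal
  }, numeric(5))
  resid <- draws - clean
  sd_target <- 0.02 * diff(range(clean))
  expect_equal(sd(as.vector(resid)), sd_target, tolerance = 0.10)
  # replicate mean converges on the noiseless curve (3 SE)
  se <- sd_target / sqrt(500)
  expect_true(all(abs(rowMeans(draws) - clean) < 3 * se))
})

test_that("binding series records equal-volume post-mix concentrations", {
  spec <- generator_spec("bimolecular_binding",
                         c(k_plus1 = 9.2e6, k_minus1 = 1.1),
                         "binding_series", seed = 3,
                         design = list(n_points = 40))
  traces <- generate_binding_series(spec, c(0.2, 2, 20) * 1e-6)
  expect_equal(vapply(traces, attr, numeric(1), "ligand_total_M"),
               c(0.1, 1, 10) * 1e-6)
  expect_equal(unique(vapply(traces, attr, numeric(1), "receptor_total_M")),
               0.2e-6)
  # irreversible limit: every trace plateaus at full occupancy
  spec0 <- generator_spec("bimolecular_binding",
                          c(k_plus1 = 9.2e6, k_minus1 = 0),
                          "binding_series", seed = 4, noise = 0,
                          design = list(t_max = 60, n_points = 40))
  tr0 <- generate_binding_series(spec0, c(0.25, 2) * 1e-6)
  for (tr in tr0) {
    base <- attr(tr, "noise")
    expect_equal(tr$signal[nrow(tr)] / max(tr$signal), 1, tolerance = 1e-3)
  }
})

test_that("condition presets round-trip through the stretched-exp fit", {
  presets <- condition_presets()
  expect_equal(presets$median_s[presets$label == "WT" & presets$nusg == "-"],
               12.4)
  cases <- list(c("WT-2AP", "-"), c("WT-2AP+NusG", "+"),
                c("mm1-2", "-"), c("3'mm", "-"),
                c("dGL+NusG", "+"), c("pyrophosphorolysis", "-"))
  for (cs in cases) {
    spec <- preset_spec(cs[[1]], seed = 42)
    target <- attr(spec, "target_median_s")
    tr <- generate_stopped_flow_trace(spec)
    f <- fit_stretched_exponential(tr)
    expect_equal(f$median_time, target, tolerance = 0.03,
                 label = paste("median for", cs[[1]]))
  }
  # pyrophosphorolysis presets generate falling traces
  pyro <- generate_stopped_flow_trace(preset_spec("pyrophosphorolysis", seed = 2))
  expect_lt(fit_stretched_exponential(pyro)$amplitude, 0)
  expect_error(preset_spec("no-such-condition"),
               class = "teckin_unknown_preset")
})

test_that("flat-contrast traces are rejected downstream as constant", {
  spec <- generator_spec("backtrack_cleavage",
                         c(k_bt = 0.5, k_fwd = 0, k_cleave = 50),
                         "stopped_flow", seed = 5,
                         observable = observable_map(
                           "fluorescence",
                           coefficients = c(TEC_pre = 1, TEC_backtracked = 1,
                                            TEC_cleaved = 1)))
  tr <- generate_stopped_flow_trace(spec)
  expect_error(fit_stretched_exponential(tr),
               class = "teckin_constant_trace")
})
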