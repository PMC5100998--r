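make_stretched_trace <- function(tau, beta, n = 200, t_max = NULL,
                                 noise = 0, seed = 1, amplitude = 1,
                                 baseline = 0) {
  t_max <- t_max %||% (6 * tau * log(2)^(1 / beta))
  t <- logspace(t_max / 2000, t_max, n)
  y <- baseline + amplitude * (1 - exp(-(t / tau)^beta))
  if (noise > 0) {
    set.seed(seed)
    y <- y + rnorm(n, 0, noise * abs(amplitude))
  }
  data.frame(time_s = t, signal = y)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("noiseless stretched-exponential fits round-trip exactly", {
  f1 <- fit_stretched_exponential(make_stretched_trace(1, 1))
  expect_equal(f1$tau, 1, tolerance = 1e-6)
  expect_equal(f1$beta, 1, tolerance = 1e-6)
  expect_equal(f1$median_time, log(2), tolerance = 1e-6)

  f2 <- fit_stretched_exponential(make_stretched_trace(1, 0.5))
  expect_equal(f2$median_time, log(2)^2, tolerance = 1e-4)
  # independent oracle: numeric half-amplitude crossing of the fitted curve
  half <- f2$baseline + f2$amplitude / 2
  root <- uniroot(function(t) predict(f2, t) - half, c(1e-4, 10))$root
  expect_equal(f2$median_time, root, tolerance = 1e-6)
})

test_that("median reaction time follows tau * log(2)^(1/beta)", {
  expect_equal(median_reaction_time(1, beta = 1), 0.6931, tolerance = 1e-4)
  expect_equal(median_reaction_time(2, beta = 1), 1.3863, tolerance = 1e-4)
  m <- median_reaction_time(1, beta = 0.8)
  expect_equal(m, log(2)^1.25, tolerance = 1e-12)
  expect_equal(m, 0.6325, tolerance = 1e-3)
  # numeric half-crossing oracle for beta != 1
  root <- uniroot(function(t) (1 - exp(-t^0.8)) - 0.5, c(1e-3, 5),
                  tol = 1e-12)$root
  expect_equal(m, root, tolerance = 1e-6)
  # property: beta = 1 reduces to the half-life for any tau
  set.seed(7)
  for (tau in 10^runif(20, -2, 2))
    expect_equal(median_reaction_time(tau, beta = 1), log(2) * tau)
  expect_error(median_reaction_time(-1), class = "teckin_bad_tau")
})

test_that("fitted curve crosses half-amplitude at the median time", {
  set.seed(11)
  for (i in 1:5) {
    tau <- 10^runif(1, -0.5, 1); beta <- runif(1, 0.6, 1.2)
    f <- fit_stretched_exponential(
      make_stretched_trace(tau, beta, noise = 0.01, seed = i))
    at_median <- predict(f, f$median_time)
    expect_equal(at_median, f$baseline + f$amplitude / 2, tolerance = 1e-9)
  }
})

test_that("median recovery is unbiased and precise on noisy traces", {
  set.seed(19)
  rel_err <- numeric(50)
  for (i in 1:50) {
    tau <- 10^runif(1, log10(0.3), log10(30))
    beta <- runif(1, 0.6, 1.0)
    noise <- runif(1, 0.01, 0.03)
    truth <- tau * log(2)^(1 / beta)
    f <- fit_stretched_exponential(
      make_stretched_trace(tau, beta, noise = noise, seed = 1000 + i))
    rel_err[i] <- (f$median_time - truth) / truth
  }
  expect_lt(abs(mean(rel_err)), 0.02)
  expect_lt(sqrt(mean(rel_err^2)), 0.05)
})

test_that("falling traces with the reference half-life recover the median", {
  # 12.4 s single-exponential decay + 1% noise (rising 2-AP analogue uses
  # positive amplitude; decays use negative amplitude)
  tr <- make_stretched_trace(12.4 / log(2), 1, noise = 0.01, seed = 5,
                             amplitude = -0.8, baseline = 2)
  f <- fit_stretched_exponential(tr)
  expect_lt(f$amplitude, 0)
  expect_equal(f$median_time, 12.4, tolerance = 0.03)
})

test_that("degenerate traces raise named errors and bound hits are flagged", {
  flat <- data.frame(time_s = 1:20, signal = rep(3, 20))
  expect_error(fit_stretched_exponential(flat),
               class = "teckin_constant_trace")
  set.seed(3)
  flat_noisy <- data.frame(time_s = 1:200,
                           signal = rnorm(200, 3, 0.01))
  expect_error(fit_stretched_exponential(flat_noisy),
               class = "teckin_constant_trace")
  short <- make_stretched_trace(1, 1, n = 5)
  expect_error(fit_stretched_exponential(short),
               class = "teckin_too_few_points")
  # strongly stretched data fit under a tighter beta floor ends on the bound
  stretched <- make_stretched_trace(1, 0.3, n = 300, t_max = 50)
  f <- fit_stretched_exponential(stretched, beta_bounds = c(0.5, 2),
                                 beta_starts = c(0.75, 1))
  expect_true(f$at_beta_bound)
})

test_that("replicate summaries follow the duplicate-range convention", {
  s1 <- summarize_replicates(12.4)
  expect_equal(s1$center, 12.4); expect_equal(s1$spread, 0)
  s2 <- summarize_replicates(c(10, 14))
  expect_equal(s2$center, 12); expect_equal(s2$spread, 4)
  s4 <- summarize_replicates(c(1, 2, 3, 4))
  expect_equal(s4$center, 2.5)
  expect_equal(s4$spread, sd(c(1, 2, 3, 4)))
  expect_equal(s4$spread, 1.2909944, tolerance = 1e-6)
  expect_error(summarize_replicates(numeric()), class = "teckin_empty_input")
})

test_that("fold changes propagate spreads to first order", {
  a <- summarize_replicates(c(30.3, 30.3))
  b <- summarize_replicates(c(12.4, 12.4))
  fc <- fold_change(a, b)
  expect_equal(fc$ratio, 30.3 / 12.4, tolerance = 1e-12)
  expect_equal(fc$ratio, 2.44, tolerance = 1e-2)
  expect_equal(fc$spread, 0)
  ident <- fold_change(summarize_replicates(c(5, 5)), summarize_replicates(c(5, 5)))
  expect_equal(ident$ratio, 1.0)
  exact <- fold_change(list(center = 2, spread = 0), list(center = 0.5, spread = 0))
  expect_equal(exact$ratio, 4.0); expect_equal(exact$spread, 0)
  expect_error(fold_change(a, list(center = 0, spread = 1)),
               class = "teckin_nonpositive_denominator")
})
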