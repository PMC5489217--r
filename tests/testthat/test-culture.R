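test_that("delay factor: closed-form values, limits and monotonicity", {
  expect_equal(delay_factor(1, 1, log(3)), 0.75)
  expect_equal(delay_factor(0.2, 0.5, 0), 0.2 / 1.2)
  expect_equal(delay_factor(0.2, 0.5, 1e6), 1)
  ts <- seq(0, 50, by = 0.5)
  f <- delay_factor(0.1, 0.2, ts)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0.1 / 1.1 - 1e-12 & f < 1))
  expect_error(delay_factor(-1, 1, 0))
})

test_that("specific rates: Monod zero, half saturation, no-production limit", {
  p <- culture_params()
  r0 <- specific_rates(p, S = 0, t = 10)
  expect_equal(r0$mu, 0)
  expect_equal(r0$qP, p$beta * delay_factor(p$q2, p$v2, 10))
  expect_equal(r0$qS, p$m + r0$qP / p$YP)
  rh <- specific_rates(p, S = p$Ks, t = 1e6)
  expect_equal(rh$mu, p$mu_max / 2, tolerance = 1e-9)
  p2 <- culture_params(alpha = 0, beta = 0)
  r2 <- specific_rates(p2, S = 4, t = 3)
  expect_equal(r2$qS, r2$mu / p2$Yo + p2$m)
})

test_that("oxygen arithmetic: qO2 and OTR", {
  expect_equal(oxygen_limited_qO2(25, 0.0075, 1), 0.1875)
  expect_error(oxygen_limited_qO2(25, 0.0075, 0), "undefined")
  # qO2 * x is the volumetric rate, independent of biomass
  for (x in c(0.5, 1, 4))
    expect_equal(oxygen_limited_qO2(25, 0.0075, x) * x, 0.1875)
  expect_equal(oxygen_limited_qO2(50, 0.0075, 2),
               2 * oxygen_limited_qO2(25, 0.0075, 2))
  expect_equal(round(otr(25, 0.0075), 1), 5.9)
  expect_equal(round(otr(15, 0.0075), 1), 3.5)
  expect_equal(otr(0), 0)
})

test_that("simulation limits: no biomass, oxygen relaxation, exponential phase", {
  p <- culture_params()
  tr <- simulate_culture(p, c(x = 0, S = 15, P = 0, C_L = 0), seq(0, 10, 0.5),
                         oxygen_limited = FALSE)
  expect_equal(tr$S, rep(15, nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$P, rep(0, nrow(tr)), tolerance = 1e-10)
  # with x = 0 the oxygen balance is linear: C_L -> C* at rate kLa
  expect_equal(tr$C_L, p$Cstar * (1 - exp(-p$kLa * tr$t)), tolerance = 1e-6)
  # vanishing delays, no maintenance, S >> Ks: pure exponential growth
  pe <- culture_params(mu_max = 0.1, Ks = 0.001, m = 0, alpha = 0,
                       beta = 0, q1 = 1e3, v1 = 50, q2 = 1e3, v2 = 50)
  te <- simulate_culture(pe, c(x = 0.1, S = 500, P = 0), seq(0, 20, 1))
  expect_equal(te$x, 0.1 * exp(0.1 * te$t), tolerance = 1e-4)
})

test_that("substrate bookkeeping closes over a full batch", {
  p <- culture_params()
  tr <- simulate_culture(p, c(x = 0.5, S = 15, P = 0), seq(0, 48, 1))
  consumed <- tr$S[1] - tr$S[nrow(tr)]
  dx <- tr$x[nrow(tr)] - tr$x[1]
  dP <- tr$P[nrow(tr)] - tr$P[1]
  # qS = mu/Yo + m + qP/YP integrates to: consumed >= dx/Yo + dP/YP
  expect_gte(consumed, dx / p$Yo + dP / p$YP - 1e-3)
  expect_true(all(tr$x >= 0 & tr$S >= 0 & tr$P >= 0))
  expect_true(all(diff(tr$S) <= 1e-9))
  expect_true(all(diff(tr$x) >= -1e-9))
})

test_that("culture TSV round trip preserves the series", {
  tr <- simulate_culture(culture_params(), c(x = 0.5, S = 15, P = 0),
                         seq(0, 20, 2))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_culture_tsv(tr, tf)
  back <- read_culture_tsv(tf)
  expect_equal(back$x, tr$x, tolerance = 1e-6)
  expect_equal(back$S, tr$S, tolerance = 1e-6)
})

test_that("yield and productivity arithmetic", {
  flat <- data.frame(t = 0:5, S = seq(10, 5, length.out = 6), P = rep(1, 6))
  yp <- yield_and_productivity(flat)
  expect_equal(yp$Y_etoh_xyl, 0)
  expect_equal(yp$Q_etoh, 0)
  ramp <- data.frame(t = 0:4, S = c(10, 8, 6, 4, 2), P = c(0, 1, 2, 3, 4))
  yp2 <- yield_and_productivity(ramp)
  expect_equal(yp2$Y_etoh_xyl, 0.5)
  expect_equal(yp2$Q_etoh, 1)
  expect_error(yield_and_productivity(
    data.frame(t = 0:1, S = c(5, 5), P = c(0, 1))), "no substrate")
  expect_equal(relative_change(120, 100), 20)
  expect_equal(relative_change(80, 100), -20)
})

test_that("fitting with everything fixed returns the inputs and the data misfit", {
  p <- culture_params()
  d <- make_culture_dataset(p, seed = 3)
  res <- fit_parameters(d, free = character())
  expect_equal(unclass(res$params), unclass(p))
  expect_true(all(res$residual_report$rmse_fraction_of_range > 0))
  expect_equal(res$k, p$q1 / p$mu_max)
})

test_that("noiseless data are refit to trajectory RMSE below 1e-3 of range", {
  p <- culture_params()
  d <- make_culture_dataset(p, sample_times = seq(0, 48, length.out = 40),
                            noise_sd = 0, seed = 1)
  res <- fit_parameters(d, n_starts = 2, seed = 1)
  expect_true(all(res$residual_report$rmse_fraction_of_range <= 1e-3))
})

test_that("parameter recovery from noisy data keeps mu_max within 10%", {
  # quick two-seed version; the full >= 10-seed median experiment runs
  # in the acceptance suite
  p <- culture_params()
  neutral <- c(mu_max = 0.05, Ks = 1, Yo = 0.4, m = 0.02, alpha = 2,
               beta = 0.02, q1 = 0.5, q2 = 0.5, v1 = 0.5, v2 = 0.5)
  errs <- vapply(c(21, 22), function(sd) {
    d <- make_culture_dataset(p, sample_times = seq(0, 48, length.out = 50),
                              seed = sd)
    f <- fit_parameters(d, init_guess = neutral, n_starts = 3, seed = sd)
    abs(f$params$mu_max - p$mu_max) / p$mu_max
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("degenerate fitting inputs error clearly", {
  d <- make_culture_dataset(culture_params(),
                            sample_times = seq(0, 8, length.out = 5),
                            seed = 1)
  expect_error(fit_parameters(d), "at least as many observations")
})
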