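# Coupling of culture rate trajectories into the FBA layer.

traj_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_culture(culture_params(), c(x = 0.5, S = 15, P = 0),
                             seq(2, 40, by = 2))
      cache <<- culture_rate_points(tr)
    }
    cache
  }
})

test_that("mass-to-mole conversions use the right molar masses", {
  out <- rates_to_constraints(0.15013, 0.032, 0.04607)
  expect_equal(out$q_xyl, 1, tolerance = 1e-9)
  expect_equal(out$q_O2, 1, tolerance = 1e-9)
  expect_equal(out$q_etoh, 1, tolerance = 1e-9)
  # round trip
  expect_equal(out$q_xyl * 150.13 / 1000, 0.15013, tolerance = 1e-12)
  expect_error(rates_to_constraints(-0.1, 0.1), "non-negative")
})

test_that("overlay maps exact nodes to themselves and predicts growth consistently", {
  g <- compute_phpp(toy_net(), carbon_axis = seq(0, 4, length.out = 9),
                    o2_axis = seq(0, 12, length.out = 9))
  nodes <- data.frame(t = 1:2, q_xyl = g$carbon_axis[c(3, 5)],
                      q_O2 = g$o2_axis[c(4, 2)],
                      mu_obs = c(0.1, 0.2), qP_obs = c(0, 0))
  ov <- overlay_trajectory(g, nodes)
  expect_equal(ov$i, c(3, 5)); expect_equal(ov$j, c(4, 2))
  expect_false(any(ov$clipped))
  # a culture trajectory: PhPP-predicted growth tracks the kinetic model
  rates <- traj_fixture()
  ov2 <- overlay_trajectory(g, rates)
  expect_gt(attr(ov2, "spearman_mu"), 0)
  # points below the grid are clipped and flagged
  low <- data.frame(t = 1, q_xyl = 2, q_O2 = 99, mu_obs = 0.1, qP_obs = 0)
  expect_message(ov3 <- overlay_trajectory(g, low), "clipped")
  expect_true(all(ov3$clipped))
  expect_error(overlay_trajectory(g, traj_fixture()[0, ]), "empty")
})

test_that("zero-fraction inhibition reproduces the uninhibited trajectory exactly", {
  rates <- traj_fixture()[seq(1, 19, by = 3), ]
  st0 <- sensitivity_trajectory(toy_net(), rates)
  st1 <- sensitivity_trajectory(toy_net(), rates,
                                inhibition_spec("CINADH", 0, 0))
  expect_equal(st1$lambda_arc_bio, st0$lambda_arc_bio, tolerance = 1e-9)
  expect_equal(st1$mu_fba, st0$mu_fba, tolerance = 1e-9)
})

test_that("trajectories differ only after the inhibition start time", {
  rates <- traj_fixture()[seq(1, 19, by = 2), ]
  st0 <- sensitivity_trajectory(toy_net(), rates)
  st1 <- sensitivity_trajectory(toy_net(), rates,
                                inhibition_spec("CINADH", 0.8, 20))
  pre <- st1$t < 20
  expect_equal(st1$mu_fba[pre], st0$mu_fba[pre], tolerance = 1e-10)
  expect_equal(st1$lambda_arc_bio[pre], st0$lambda_arc_bio[pre],
               tolerance = 1e-10)
  expect_true(any(st1$mu_fba[!pre] < st0$mu_fba[!pre] - 1e-6))
  # the cap never improves biomass anywhere
  expect_true(all(st1$mu_fba <= st0$mu_fba + 1e-9))
})

test_that("microaerobic uninhibited trajectory keeps ARC limiting for ethanol", {
  rates <- traj_fixture()
  st <- sensitivity_trajectory(toy_net(), rates)
  expect_true(all(st$status == "optimal"))
  expect_true(all(st$lambda_arc_etoh < 0))
})

test_that("infeasible points are recorded and the trajectory continues", {
  # forced maintenance with no carbon makes early points infeasible
  net <- make_core_network(toy_network_options(ngam = 1))
  rates <- data.frame(t = c(1, 2), q_xyl = c(0, 10), q_O2 = c(0, 10),
                      mu_obs = 0, qP_obs = 0)
  st <- sensitivity_trajectory(net, rates)
  expect_identical(st$status, c("infeasible", "optimal"))
  expect_true(is.na(st$lambda_arc_bio[1]))
})

test_that("the inhibition flux report ranks complex I among the top reductions", {
  rates <- traj_fixture()
  rep <- inhibition_flux_report(toy_net(), rates,
                                inhibition_spec("CINADH", 0.8, 0))
  expect_true("CINADH" %in% names(rep$diff$decreased)[1:3])
  inc <- subset(rep$table, group == "increased")
  expect_true(any(inc$subsystem %in%
                  c("Glycolysis", "Fermentation", "TCA cycle",
                    "Glycerol metabolism", "Transport", "Exchange")))
  expect_true(all(diff(subset(rep$table, group == "decreased")$flux_shift) <= 0))
  # no inhibition, no differences
  rep0 <- inhibition_flux_report(toy_net(), rates,
                                 inhibition_spec("CINADH", 0, 0))
  expect_length(rep0$diff$turned_on, 0)
  expect_length(rep0$diff$increased, 0)
})
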