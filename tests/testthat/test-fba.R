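test_that("optimal solutions satisfy steady state and strong duality", {
  for (o2 in c(40, 8, 3)) {
    net <- with_uptakes(toy_net(), 10, o2)
    sol <- solve_fba(net)
    expect_identical(sol$status, "optimal")
    S <- stoich_matrix(net)
    v <- sol$fluxes[colnames(S)]
    expect_lt(max(abs(S %*% v)), 1e-6)
    # strong duality for the bounded LP: primal objective equals the
    # dual objective y'b + sum_j d_j^+ u_j + d_j^- l_j with reduced
    # costs d = c - S'y split by sign
    bd <- reaction_bounds(net)
    cvec <- as.numeric(bd$id == sol$objective_id)
    d <- cvec - as.numeric(crossprod(S, sol$duals[rownames(S)]))
    dual_obj <- sum(pmax(d, 0) * bd$upper_bound) +
                sum(pmin(d, 0) * bd$lower_bound)
    expect_equal(dual_obj, sol$objective_value, tolerance = 1e-6)
  }
})

test_that("no carbon means no growth and an empty flux-carrying set", {
  net <- with_uptakes(toy_net(), 0, 0)
  net <- set_uptake(net, "EX_glc", 0)
  sol <- solve_fba(net)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  expect_length(flux_carrying_set(sol), 0)
  expect_length(flux_carrying_set(solve_fba(with_uptakes(toy_net(), 10, 8)),
                                  tol = Inf), 0)
})

test_that("finite-difference dual oracle passes at three metabolic states", {
  # >= 95% of metabolites must agree or be flagged degenerate, never
  # silently wrong
  for (o2 in c(40, 8, 3)) {
    net <- with_uptakes(toy_net(), 10, o2)
    fd <- dual_sensitivity_fd(net)
    ok <- fd$agree | fd$degenerate
    expect_gte(mean(ok), 0.95)
    expect_true(all(ok), info = paste("state o2 =", o2, "failing:",
      paste(fd$metabolite[!ok], collapse = ",")))
  }
})

test_that("growth is concave along an oxygen section (LP value function)", {
  net <- toy_net()
  o2s <- seq(0, 24, by = 2)
  mus <- vapply(o2s, function(o) solve_fba(with_uptakes(net, 10, o))$objective_value, 0)
  mid <- (mus[-c(1, length(mus))])
  chords <- (mus[-c(length(mus) - 1, length(mus))] + mus[-c(1, 2)]) / 2
  expect_true(all(mid >= chords - 1e-8))
})

test_that("loop removal zeroes an injected futile cycle without moving the objective", {
  net <- futile_cycle_network()
  sol <- solve_fba(with_uptakes(net, 10, 8))
  # inject an arbitrary circulation around the internal 3-cycle: still
  # feasible (the cycle is stoichiometrically balanced), same objective
  sol_loopy <- sol
  sol_loopy$fluxes[c("CYC1", "CYC2", "CYC3")] <-
    sol_loopy$fluxes[c("CYC1", "CYC2", "CYC3")] + 123.4
  S <- stoich_matrix(net)
  expect_lt(max(abs(S %*% sol_loopy$fluxes[colnames(S)])), 1e-6)
  clean <- enforce_loopless(net, sol_loopy)
  expect_equal(unname(clean$fluxes[c("CYC1", "CYC2", "CYC3")]), rep(0, 3))
  expect_equal(clean$fluxes[[sol$objective_id]], sol$objective_value,
               tolerance = 1e-8)
  expect_equal(clean$fluxes[exchange_ids(net)],
               sol$fluxes[exchange_ids(net)], tolerance = 1e-8)
})

test_that("loop removal is the identity when no cycles are carried", {
  net <- with_uptakes(toy_net(), 10, 8)
  sol <- solve_fba(net)
  clean <- enforce_loopless(net, sol)
  expect_equal(clean$fluxes, sol$fluxes, tolerance = 1e-9)
  sol2 <- solve_fba(net, loopless = TRUE)
  expect_true(isTRUE(sol2$loopless))
  expect_equal(sol2$objective_value, sol$objective_value, tolerance = 1e-10)
})

test_that("flux-carrying-set diffs classify a complex I cap as the field expects", {
  base <- with_uptakes(toy_net(), 10, 8)
  s_ref <- solve_fba(base)
  expect_length(compare_fcs(s_ref, s_ref)$increased, 0)
  capped <- inhibit(base, "CINADH", 0.8, abs(s_ref$fluxes[["CINADH"]]))
  s_alt <- solve_fba(capped)
  d <- compare_fcs(s_ref, s_alt)
  expect_true("CINADH" %in% names(d$decreased))
  # the capped complex I shows one of the largest reductions (in this
  # lumped network the ATP synthase, which carries ~1.5x the chain flux
  # and has no compensating ATP source, tracks it closely)
  expect_true("CINADH" %in% names(d$decreased)[1:3])
  ferm <- c("PDC", "ADH", "ETOHt", "EX_etoh", "GLYC_X", "GPD_X")
  expect_true(any(ferm %in% names(d$increased)))
  # groups partition: disjoint, subset of the reaction universe
  groups <- list(d$turned_on, d$turned_off, names(d$increased),
                 names(d$decreased))
  all_ids <- unlist(groups)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_true(all(all_ids %in% names(s_ref$fluxes)))
  expect_error(compare_fcs(s_ref, list(fluxes = s_ref$fluxes[-1])),
               "different reaction sets")
})
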