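# Shared fixtures: networks and an independent brute-force LP oracle.

toy_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_core_network()
    cache
  }
})

with_uptakes <- function(net, q_xyl, q_o2, carbon = "EX_xyl") {
  net <- set_uptake(net, carbon, q_xyl)
  if (carbon != "EX_xyl") net <- set_uptake(net, "EX_xyl", 0)
  set_uptake(net, "EX_o2", q_o2)
}

# Aerobic biomass yield of the toy network per mmol xylose, derived by
# hand from the lumped stoichiometry (see test-toy-network.R for the
# derivation); frozen here as the independent oracle value.
TOY_MU_PER_XYL <- 12.333333333333334 / 156

# toy network augmented with a three-reaction internal futile cycle
# A -> B -> C -> A on otherwise disconnected metabolites
futile_cycle_network <- function() {
  net <- toy_net()
  mets <- rbind(net$metabolites,
                metabolite("cycA_c", "cycle A", "c", 0),
                metabolite("cycB_c", "cycle B", "c", 0),
                metabolite("cycC_c", "cycle C", "c", 0))
  rxns <- c(net$reactions, list(
    reaction("CYC1", c(cycA_c = -1, cycB_c = 1), 0, 1000, subsystem = "Cycle"),
    reaction("CYC2", c(cycB_c = -1, cycC_c = 1), 0, 1000, subsystem = "Cycle"),
    reaction("CYC3", c(cycC_c = -1, cycA_c = 1), 0, 1000, subsystem = "Cycle")))
  metabolic_network(mets, rxns, net$objective_id, net$compartments)
}

# tiny two-path network whose growth rate is linear in the carbon
# uptake and independent of the second axis: a single phenotypic phase
single_phase_network <- function() {
  mets <- rbind(metabolite("A_e", "substrate", "e", 1),
                metabolite("O_e", "unused gas", "e", 0),
                metabolite("P_e", "unmakeable product", "e", 1),
                metabolite("biomass_e", "biomass", "e", 1))
  rxns <- list(
    reaction("EX_A", c(A_e = -1), -10, 1000, is_exchange = TRUE),
    reaction("EX_O", c(O_e = -1), -10, 0, is_exchange = TRUE),
    reaction("EX_etoh", c(P_e = -1), 0, 1000, is_exchange = TRUE),
    reaction("EX_biomass", c(biomass_e = -1), 0, 1000, is_exchange = TRUE),
    reaction("GROW", c(A_e = -1, biomass_e = 1), 0, 1000))
  metabolic_network(mets, rxns, "GROW")
}

# Brute-force LP oracle: enumerate bases x bound assignments, return
# the best feasible vertex.  Only for tiny systems; independent of the
# simplex implementation.
lp_oracle <- function(A, b, obj, lb, ub, sense = "max") {
  m <- nrow(A); n <- ncol(A)
  best <- NULL; bestz <- if (sense == "max") -Inf else Inf
  combos <- utils::combn(n, m)
  for (ci in seq_len(ncol(combos))) {
    bas <- combos[, ci]
    B <- A[, bas, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nb <- setdiff(seq_len(n), bas)
    grid <- expand.grid(rep(list(c(0, 1)), length(nb)))
    for (gi in seq_len(max(1L, nrow(grid)))) {
      x <- numeric(n)
      if (length(nb))
        x[nb] <- ifelse(grid[gi, ] == 0, lb[nb], ub[nb])
      x[bas] <- solve(B, b - A[, nb, drop = FALSE] %*% x[nb])
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      z <- sum(obj * x)
      if ((sense == "max" && z > bestz) || (sense == "min" && z < bestz)) {
        bestz <- z; best <- x
      }
    }
  }
  list(objective = bestz, x = best)
}
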