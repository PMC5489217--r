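# ARC (available reducing capacity) sensitivity analysis.
#
# The sensitivity of an objective Z to the NAD(H/+) redox pair is the
# difference of the two shadow prices,
#
#     lambda_ARC^Z = lambda_NADH^Z - lambda_NAD^Z,
#
# the net response of Z to moving one reducing equivalent into the pool
# (adding NADH while removing NAD+).  lambda_ARC < 0 means reducing
# capacity limits Z, > 0 means it is in excess, = 0 no effect.  The
# identity is exact arithmetic on stored duals; the joint perturbation
# is validated independently by [arc_sensitivity_fd()].

.classify_lambda <- function(l, band) {
  ifelse(is.na(l), NA_character_,
         ifelse(l < -band, "limiting", ifelse(l > band, "excess", "no_effect")))
}

.cofactor_ids <- function(available, compartment) {
  nadh <- paste0("nadh_", compartment)
  nad <- paste0("nad_", compartment)
  missing <- setdiff(c(nadh, nad), available)
  if (length(missing))
    stop("NAD(H) metabolite id(s) ", paste(missing, collapse = ", "),
         " not found; available cofactor-like ids: ",
         paste(grep("^nadp?h?_", available, value = TRUE), collapse = ", "))
  c(nadh = nadh, nad = nad)
}

#' ARC sensitivity record from an FBA solution
#'
#' Reads lambda_NADH and lambda_NAD from the solution's dual vector for
#' each requested compartment and forms lambda_ARC = lambda_NADH -
#' lambda_NAD.  Cofactors are located by the naming convention
#' `nadh_<compartment>` / `nad_<compartment>`.  A pooled value (sum over
#' the requested compartments) is reported alongside; the scalar
#' `lambda_arc_default` is the cytosolic value when present, else the
#' first compartment's.
#'
#' @param solution an optimal `fba_solution` with duals.
#' @param compartments compartment codes (default cytosol and
#'   mitochondrion).
#' @param zero_band classification half-width: `|lambda| <= zero_band`
#'   counts as "no_effect" (default `1e-6`).
#' @return object of class `"sensitivity_record"` with per-compartment
#'   `lambda_nadh`, `lambda_nad`, `lambda_arc`, `classification`, plus
#'   `lambda_arc_pooled` and `lambda_arc_default`.
#' @export
arc_sensitivity <- function(solution, compartments = c("c", "m"),
                            zero_band = 1e-6) {
  if (!identical(solution$status, "optimal"))
    stop("arc_sensitivity requires an optimal solution with duals")
  duals <- solution$duals
  lam_nadh <- lam_nad <- stats::setNames(numeric(length(compartments)),
                                         compartments)
  for (cp in compartments) {
    ids <- .cofactor_ids(names(duals), cp)
    lam_nadh[cp] <- duals[[ids[["nadh"]]]]
    lam_nad[cp] <- duals[[ids[["nad"]]]]
  }
  lam_arc <- lam_nadh - lam_nad
  default_cp <- if ("c" %in% compartments) "c" else compartments[1]
  structure(list(objective_id = solution$objective_id,
                 compartments = compartments,
                 lambda_nadh = lam_nadh,
                 lambda_nad = lam_nad,
                 lambda_arc = lam_arc,
                 lambda_arc_pooled = sum(lam_arc),
                 lambda_arc_default = lam_arc[[default_cp]],
                 classification = .classify_lambda(lam_arc, zero_band),
                 zero_band = zero_band),
            class = "sensitivity_record")
}

#' @export
print.sensitivity_record <- function(x, ...) {
  cat("ARC sensitivity for objective", x$objective_id, "\n")
  for (cp in x$compartments)
    cat(sprintf("  [%s] lambda_NADH = %+.6g  lambda_NAD = %+.6g  lambda_ARC = %+.6g (%s)\n",
                cp, x$lambda_nadh[[cp]], x$lambda_nad[[cp]],
                x$lambda_arc[[cp]], x$classification[[cp]]))
  cat(sprintf("  pooled lambda_ARC = %+.6g\n", x$lambda_arc_pooled))
  invisible(x)
}

# Internal bi-level solve shared by the sensitivity and PhPP layers.
# Step 1 maximises biomass at the given bounds; step 2 maximises the
# secondary objective with the biomass flux pinned to its optimum
# (relative tolerance fix_tol, retried once at retry_tol when the
# fixing is numerically over-tight).  fix_scope = "state" instead pins
# every flux of the step-1 vertex (the literal reading of fixing "all
# flux values associated to that state"); that collapses step 2 to a
# point whose duals are all zero, so it is not the default.
.bilevel_solve <- function(lp, biomass_id, secondary_id,
                           fix_tol = 1e-9, retry_tol = 1e-4,
                           fix_scope = "biomass") {
  s1 <- .fba_solve_lp(lp, biomass_id)
  if (s1$status != "optimal")
    return(list(step1 = s1, step2 = NULL))
  jb <- match(biomass_id, lp$rxn_ids)
  # the pin leaves a sliver of downward slack so the step-2 LP stays
  # full-dimensional (its duals are the state's sensitivities); the
  # ladder widens the slack only if the solver reports infeasibility
  for (tol in c(fix_tol, 1e-6, retry_tol)) {
    lp2 <- lp
    if (identical(fix_scope, "state")) {
      v0 <- s1$fluxes
      lp2$lb <- pmax(lp$lb, v0 - tol * pmax(1, abs(v0)))
      lp2$ub <- pmin(lp$ub, v0 + tol * pmax(1, abs(v0)))
    } else {
      # no upper cap: the step-1 optimum already bounds the flux from
      # above, and capping at it would shift dual weight onto the bound
      lp2$lb[jb] <- max(lp$lb[jb], s1$objective_value * (1 - tol))
    }
    s2 <- .fba_solve_lp(lp2, secondary_id)
    if (s2$status == "optimal")
      return(list(step1 = s1, step2 = s2))
  }
  stop("secondary-objective LP infeasible even at relaxed fixing tolerance ",
       retry_tol)
}

.apply_uptakes <- function(network, uptakes) {
  for (nm in names(uptakes))
    network <- set_uptake(network, nm, uptakes[[nm]])
  network
}

#' Bi-level objective sensitivity at a metabolic state
#'
#' Implements the two-stage procedure used throughout the PhPP
#' analysis: (1) FBA maximising biomass at the given uptake bounds
#' selects a metabolic state with biological sense; (2) a second LP
#' maximises a secondary objective (by default the ethanol exchange)
#' with the biomass flux fixed at its step-1 optimum and the same
#' uptake bounds.  ARC sensitivities are read from the step-2 duals.
#'
#' @param network a [metabolic_network()].
#' @param uptakes named list/vector, exchange id -> maximal uptake rate.
#' @param secondary_objective_id reaction maximised in step 2
#'   (default `"EX_etoh"`).
#' @param compartments passed to [arc_sensitivity()].
#' @param fix_tol relative tolerance for pinning the biomass flux
#'   (default `1e-9`; widened stepwise to `1e-4` if the pin proves
#'   numerically over-tight).
#' @param fix_scope `"biomass"` (default) pins only the biomass flux;
#'   `"state"` pins every flux of the step-1 vertex, which makes all
#'   step-2 duals vanish identically.
#' @param zero_band classification band for [arc_sensitivity()].
#' @return list with `mu` (step-1 optimum), `secondary_flux` (step-2
#'   optimum), `sensitivity` (a `sensitivity_record`), `status`, and
#'   the two solutions `solution_biomass`, `solution_secondary`.
#' @export
objective_sensitivity_at_state <- function(network, uptakes,
                                           secondary_objective_id = "EX_etoh",
                                           compartments = c("c", "m"),
                                           fix_tol = 1e-9,
                                           fix_scope = c("biomass", "state"),
                                           zero_band = 1e-6) {
  fix_scope <- match.arg(fix_scope)
  net <- .apply_uptakes(network, uptakes)
  lp <- .fba_lp(net)
  res <- .bilevel_solve(lp, net$objective_id, secondary_objective_id,
                        fix_tol = fix_tol, fix_scope = fix_scope)
  if (is.null(res$step2))
    return(list(mu = NA_real_, secondary_flux = NA_real_, sensitivity = NULL,
                status = res$step1$status,
                solution_biomass = res$step1, solution_secondary = NULL))
  rec <- arc_sensitivity(res$step2, compartments, zero_band)
  list(mu = res$step1$objective_value,
       secondary_flux = res$step2$objective_value,
       sensitivity = rec, status = "optimal",
       solution_biomass = res$step1, solution_secondary = res$step2)
}

#' Single-level biomass ARC sensitivity
#'
#' FBA maximising biomass at the given uptakes; lambda_ARC read
#' directly from its duals.
#'
#' @inheritParams objective_sensitivity_at_state
#' @return list with `mu`, `sensitivity`, `status`, `solution`.
#' @export
biomass_arc_sensitivity <- function(network, uptakes,
                                    compartments = c("c", "m"),
                                    zero_band = 1e-6) {
  net <- .apply_uptakes(network, uptakes)
  sol <- solve_fba(net)
  if (sol$status != "optimal")
    return(list(mu = NA_real_, sensitivity = NULL, status = sol$status,
                solution = sol))
  list(mu = sol$objective_value,
       sensitivity = arc_sensitivity(sol, compartments, zero_band),
       status = "optimal", solution = sol)
}

#' Finite-difference oracle for lambda_ARC
#'
#' Estimates the ARC sensitivity by the joint perturbation the index is
#' defined by: a small NADH source together with an equal NAD+ sink in
#' the requested compartment, re-solving the (optionally bi-level)
#' problem and returning `-(Z(eps) - Z(0)) / eps`.  At non-degenerate
#' optima this agrees with the dual-based lambda_ARC within
#' first-order accuracy.
#'
#' @inheritParams objective_sensitivity_at_state
#' @param compartment single compartment code.
#' @param eps perturbation size (default `1e-4`).
#' @param bilevel if `TRUE` perturb the step-2 (ethanol) LP of the
#'   bi-level procedure, else the single-level biomass LP.
#' @param fix_tol biomass-pin slack held fixed while perturbing
#'   (default `1e-3`, deliberately wider than the analysis default so
#'   the perturbed LP stays feasible over the whole `eps` excursion;
#'   duals do not depend on a bound's value while the same basis stays
#'   optimal, so the estimate remains comparable).
#' @return the finite-difference lambda_ARC estimate (scalar).
#' @export
arc_sensitivity_fd <- function(network, uptakes, compartment = "c",
                               eps = 1e-4, bilevel = FALSE,
                               secondary_objective_id = "EX_etoh",
                               fix_tol = 1e-3) {
  net <- .apply_uptakes(network, uptakes)
  lp <- .fba_lp(net)
  ids <- .cofactor_ids(lp$met_ids, compartment)
  i_nadh <- match(ids[["nadh"]], lp$met_ids)
  i_nad <- match(ids[["nad"]], lp$met_ids)
  if (bilevel) {
    # pin biomass at the unperturbed step-1 optimum, then perturb the
    # step-2 LP: the sensitivity belongs to the state, not to a
    # re-optimised one
    s1 <- .fba_solve_lp(lp, net$objective_id)
    if (s1$status != "optimal") return(NA_real_)
    jb <- match(net$objective_id, lp$rxn_ids)
    lp$lb[jb] <- max(lp$lb[jb], s1$objective_value * (1 - fix_tol))
    objective_id <- secondary_objective_id
  } else {
    objective_id <- net$objective_id
  }
  solve_z <- function(lpx) {
    s <- .fba_solve_lp(lpx, objective_id)
    if (s$status != "optimal") NA_real_ else s$objective_value
  }
  z0 <- solve_z(lp)
  lp2 <- lp
  lp2$b[i_nadh] <- -eps   # availability of NADH raised by eps
  lp2$b[i_nad] <- eps     # availability of NAD+ lowered by eps
  z1 <- solve_z(lp2)
  -(z1 - z0) / eps
}
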