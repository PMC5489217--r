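# Coupling of culture rate trajectories into FBA.
#
# Quasi-static coupling: each time point of a fitted (or simulated)
# batch culture supplies xylose and oxygen uptake rates, which bound an
# independent steady-state FBA; metabolic states are calculated
# successively along the culture, with no dynamic feedback.  Respiratory
# inhibition is simulated by capping the target reaction's upper bound
# at a fraction of its flux in the matching uninhibited optimum.

MW_XYLOSE <- 150.13
MW_O2 <- 32.00
MW_ETOH <- 46.07

#' Convert mass-based specific rates to mmol-based FBA constraints
#'
#' @param qS xylose uptake in g/gcell/h.
#' @param qO2 oxygen uptake in g/gcell/h.
#' @param qP ethanol production in g/gcell/h (optional).
#' @return list with `q_xyl`, `q_O2` (and `q_etoh` when `qP` given) in
#'   mmol/gDW/h; biomass is taken as dry weight.
#' @export
rates_to_constraints <- function(qS, qO2, qP = NULL) {
  if (any(qS < 0) || any(qO2 < 0) || (!is.null(qP) && any(qP < 0)))
    stop("specific rates must be non-negative")
  out <- list(q_xyl = qS / MW_XYLOSE * 1000, q_O2 = qO2 / MW_O2 * 1000)
  if (!is.null(qP)) out$q_etoh <- qP / MW_ETOH * 1000
  out
}

#' Rate points from a culture trajectory
#'
#' Extracts (t, q_xyl, q_O2, mu_obs, qP_obs) from a
#' [simulate_culture()] trajectory (or a fitted model evaluated on a
#' time grid), converting to mmol/gDW/h.
#'
#' @param trajectory a `culture_trajectory`.
#' @param times optional subset of times (nearest rows are used).
#' @return `data.frame` with columns `t`, `q_xyl`, `q_O2`, `mu_obs`,
#'   `qP_obs`.
#' @export
culture_rate_points <- function(trajectory, times = NULL) {
  tr <- trajectory
  if (!is.null(times))
    tr <- tr[vapply(times, function(tt) which.min(abs(tr$t - tt)), 1L), ]
  conv <- rates_to_constraints(pmax(tr$qS, 0), pmax(tr$qO2, 0),
                               pmax(tr$qP, 0))
  data.frame(t = tr$t, q_xyl = conv$q_xyl, q_O2 = conv$q_O2,
             mu_obs = tr$mu, qP_obs = conv$q_etoh)
}

#' Overlay a culture trajectory on a PhPP
#'
#' Maps every rate point to its nearest grid cell (clipping to the grid
#' ranges, with clipped points flagged) and reports that cell's
#' PhPP-predicted growth rate, ethanol productivity and phase label
#' next to the observed rates.
#'
#' @param grid a `phpp_grid`.
#' @param rates a `data.frame` of rate points ([culture_rate_points()]).
#' @return `data.frame` with the mapped indices, predictions,
#'   observations and a `clipped` flag; attribute `"spearman_mu"` holds
#'   the rank correlation between predicted and observed growth rate.
#' @export
overlay_trajectory <- function(grid, rates) {
  if (is.null(rates) || nrow(rates) == 0L) stop("empty rate trajectory")
  snap <- function(ax, v) which.min(abs(ax - v))
  out <- do.call(rbind, lapply(seq_len(nrow(rates)), function(k) {
    qc <- rates$q_xyl[k]; qo <- rates$q_O2[k]
    clipped <- qc < min(grid$carbon_axis) || qc > max(grid$carbon_axis) ||
               qo < min(grid$o2_axis) || qo > max(grid$o2_axis)
    i <- snap(grid$carbon_axis, qc); j <- snap(grid$o2_axis, qo)
    data.frame(t = rates$t[k], q_xyl = qc, q_O2 = qo, i = i, j = j,
               clipped = clipped,
               mu_phpp = grid$mu_surface[i, j],
               qetoh_phpp = grid$qetoh_surface[i, j],
               phase = grid$phase_labels[i, j],
               mu_obs = rates$mu_obs[k], qP_obs = rates$qP_obs[k])
  }))
  if (any(out$clipped))
    message(sum(out$clipped), " rate point(s) outside the grid were clipped")
  ok <- stats::complete.cases(out[, c("mu_phpp", "mu_obs")])
  if (sum(ok) >= 3L && stats::sd(out$mu_phpp[ok]) > 0 &&
      stats::sd(out$mu_obs[ok]) > 0)
    attr(out, "spearman_mu") <- stats::cor(out$mu_phpp[ok], out$mu_obs[ok],
                                           method = "spearman")
  out
}

#' Specification of a simulated respiratory inhibition
#'
#' @param reaction_id reaction to cap (default `"CINADH"`, the
#'   rotenone target).
#' @param fraction inhibited fraction in `[0, 1]` (default 0.8).
#' @param start_time time (h) from which the cap applies.
#' @return list of class `"inhibition_spec"`.
#' @export
inhibition_spec <- function(reaction_id = "CINADH", fraction = 0.8,
                            start_time = 0) {
  stopifnot(fraction >= 0, fraction <= 1)
  structure(list(reaction_id = reaction_id, fraction = fraction,
                 start_time = start_time), class = "inhibition_spec")
}

# Internal: one trajectory point -> uptake-bounded network (+ optional cap).
.point_network <- function(network, carbon_exchange_id, o2_exchange_id,
                           q_xyl, q_O2, inhibition = NULL, active = FALSE) {
  net <- set_uptake(set_uptake(network, carbon_exchange_id, q_xyl),
                    o2_exchange_id, q_O2)
  ref <- NA_real_
  # a zero inhibited fraction is a true no-op: even a cap placed exactly
  # at the optimal flux would perturb the dual solution
  if (!is.null(inhibition) && active && inhibition$fraction > 0) {
    s_ref <- solve_fba(net)
    if (s_ref$status == "optimal") {
      ref <- abs(s_ref$fluxes[[inhibition$reaction_id]])
      net <- inhibit(net, inhibition$reaction_id, inhibition$fraction, ref)
    }
  }
  list(network = net, reference_flux = ref)
}

#' ARC sensitivity trajectory along culture rates
#'
#' For every rate point, bounds the carbon and oxygen uptakes, applies
#' the inhibition cap when active (t >= start time; the cap is
#' `(1 - fraction)` times the reaction's flux in the uninhibited
#' optimum at the same uptakes, recomputed per point), and records the
#' single-level biomass ARC sensitivity and the bi-level ethanol ARC
#' sensitivity.  Each point is an independent LP; infeasible points are
#' recorded and the trajectory continues.
#'
#' @param network a [metabolic_network()].
#' @param rates rate points ([culture_rate_points()]).
#' @param inhibition optional [inhibition_spec()].
#' @param carbon_exchange_id,o2_exchange_id scanned exchanges.
#' @param compartment compartment for the reported lambda values.
#' @return `data.frame` of class `"sensitivity_trajectory"`: `t`,
#'   `lambda_arc_bio`, `lambda_arc_etoh`, `mu_fba`, `qetoh_fba`,
#'   `inhibited`, `status`.
#' @export
sensitivity_trajectory <- function(network, rates, inhibition = NULL,
                                   carbon_exchange_id = "EX_xyl",
                                   o2_exchange_id = "EX_o2",
                                   compartment = "c") {
  stopifnot(nrow(rates) > 0)
  rows <- lapply(seq_len(nrow(rates)), function(k) {
    active <- !is.null(inhibition) && rates$t[k] >= inhibition$start_time
    pt <- .point_network(network, carbon_exchange_id, o2_exchange_id,
                         rates$q_xyl[k], rates$q_O2[k], inhibition, active)
    lp <- .fba_lp(pt$network)
    res <- tryCatch(
      .bilevel_solve(lp, network$objective_id, "EX_etoh"),
      error = function(e) NULL)
    if (is.null(res) || res$step1$status != "optimal")
      return(data.frame(t = rates$t[k], lambda_arc_bio = NA_real_,
                        lambda_arc_etoh = NA_real_, mu_fba = NA_real_,
                        qetoh_fba = NA_real_, inhibited = active,
                        status = if (is.null(res)) "error"
                                 else res$step1$status))
    rec_bio <- arc_sensitivity(res$step1, compartment)
    rec_etoh <- if (!is.null(res$step2)) arc_sensitivity(res$step2, compartment)
    data.frame(t = rates$t[k],
               lambda_arc_bio = rec_bio$lambda_arc[[compartment]],
               lambda_arc_etoh = if (is.null(rec_etoh)) NA_real_
                                 else rec_etoh$lambda_arc[[compartment]],
               mu_fba = res$step1$objective_value,
               qetoh_fba = if (is.null(res$step2)) NA_real_
                           else res$step2$objective_value,
               inhibited = active, status = "optimal")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_trajectory", "data.frame")
  attr(out, "inhibition") <- inhibition
  out
}

#' Flux-change report for a simulated inhibition
#'
#' Solves the matched uninhibited and inhibited FBA at one
#' representative time point (default: the point of maximal observed
#' ethanol productivity) and classifies the flux changes with
#' [compare_fcs()], mirroring a largest-shift table.
#'
#' @inheritParams sensitivity_trajectory
#' @param time_point representative time (h); default the `qP_obs`
#'   maximum.
#' @param tol flux threshold for [compare_fcs()].
#' @return list with `diff` (an `fcs_diff`), `table` (a sorted
#'   `data.frame` with shift, reaction name, formula and subsystem),
#'   `time_point`, `reference_flux`.
#' @export
inhibition_flux_report <- function(network, rates, inhibition,
                                   time_point = NULL,
                                   carbon_exchange_id = "EX_xyl",
                                   o2_exchange_id = "EX_o2", tol = 1e-6) {
  stopifnot(inherits(inhibition, "inhibition_spec"))
  if (is.null(time_point)) time_point <- rates$t[which.max(rates$qP_obs)]
  k <- which.min(abs(rates$t - time_point))
  base <- set_uptake(set_uptake(network, carbon_exchange_id,
                                rates$q_xyl[k]),
                     o2_exchange_id, rates$q_O2[k])
  s_ref <- solve_fba(base)
  if (s_ref$status != "optimal")
    stop("uninhibited FBA not optimal at t = ", rates$t[k])
  ref <- abs(s_ref$fluxes[[inhibition$reaction_id]])
  net_inh <- inhibit(base, inhibition$reaction_id, inhibition$fraction, ref)
  s_inh <- solve_fba(net_inh)
  if (s_inh$status != "optimal")
    stop("inhibited FBA not optimal at t = ", rates$t[k])
  d <- compare_fcs(s_ref, s_inh, tol)
  fmt_rxn <- function(id) {
    rx <- network$reactions[[id]]
    st <- rx$stoich
    lhs <- paste(sprintf("%g %s", -st[st < 0], names(st)[st < 0]),
                 collapse = " + ")
    rhs <- paste(sprintf("%g %s", st[st > 0], names(st)[st > 0]),
                 collapse = " + ")
    data.frame(reaction = id, name = rx$name,
               formula = paste(lhs, "->", rhs), subsystem = rx$subsystem)
  }
  mk_table <- function(ids, shifts, group) {
    if (!length(ids)) return(NULL)
    cbind(data.frame(group = group,
                     flux_shift = if (is.null(shifts)) NA_real_ else shifts),
          do.call(rbind, lapply(ids, fmt_rxn)))
  }
  tab <- rbind(
    mk_table(names(d$decreased), as.numeric(d$decreased), "decreased"),
    mk_table(names(d$increased), as.numeric(d$increased), "increased"),
    mk_table(d$turned_off, rep(NA_real_, length(d$turned_off)), "turned_off"),
    mk_table(d$turned_on, rep(NA_real_, length(d$turned_on)), "turned_on"))
  list(diff = d, table = tab, time_point = rates$t[k], reference_flux = ref)
}
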