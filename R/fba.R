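# Flux balance analysis engine.
#
# Solves max/min c'v subject to S v = 0 and flux bounds, returns the
# primal flux vector together with the metabolite shadow-price vector
# lambda, and provides loop-removing post-processing and flux-carrying
# set comparison.
#
# Shadow-price sign convention: lambda_i = -dZ/d(availability of i), so
# lambda_i < 0 means metabolite i is limiting (adding it increases the
# objective), lambda_i > 0 means it is in excess, lambda_i = 0 no
# effect.  Under S v = b with b_i the required net production, an
# availability increase a corresponds to b_i = -a, hence lambda equals
# the classical equality-row dual of the maximisation LP.  The mapping
# is validated against a finite-difference oracle in the test suite and
# via [dual_sensitivity_fd()], not assumed.

# Internal: assemble the LP data for a network.
.fba_lp <- function(network) {
  S <- stoich_matrix(network)
  bd <- reaction_bounds(network)
  list(S = S, b = rep(0, nrow(S)), lb = bd$lower_bound, ub = bd$upper_bound,
       rxn_ids = bd$id, met_ids = rownames(S),
       is_exchange = vapply(network$reactions, `[[`, TRUE, "is_exchange"))
}

.fba_objvec <- function(lp, objective_id) {
  j <- match(objective_id, lp$rxn_ids)
  if (is.na(j)) stop("objective '", objective_id, "' not in network")
  obj <- numeric(length(lp$rxn_ids))
  obj[j] <- 1
  obj
}

# Internal: solve the LP in `lp` for a unit objective on `objective_id`.
.fba_solve_lp <- function(lp, objective_id, sense = "max") {
  obj <- .fba_objvec(lp, objective_id)
  r <- lp_solve(lp$S, lp$b, obj, lp$lb, lp$ub, sense = sense)
  sol <- list(status = r$status,
              objective_value = r$objective,
              fluxes = stats::setNames(r$x, lp$rxn_ids),
              duals = stats::setNames(r$y, lp$met_ids),
              objective_id = objective_id,
              sense = sense,
              is_exchange = stats::setNames(lp$is_exchange, lp$rxn_ids))
  class(sol) <- "fba_solution"
  sol
}

#' Solve a flux balance analysis problem
#'
#' Maximises (or minimises) the flux through `objective_id` subject to
#' steady state `S v = 0` and the network's flux bounds.  The returned
#' solution carries the optimal vertex fluxes and the metabolite dual
#' (shadow-price) vector; repeated calls on identical input return
#' identical solutions (fixed pivoting rules, fixed variable order).
#'
#' @param network a [metabolic_network()].
#' @param objective_id reaction whose flux is optimised; defaults to the
#'   network's declared objective.
#' @param sense `"max"` (default) or `"min"`.
#' @param loopless if `TRUE`, post-process with [enforce_loopless()]
#'   (objective and exchange fluxes preserved; duals from the plain LP,
#'   as duals are only defined for the LP relaxation).
#' @return an `fba_solution` with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value`, `fluxes`, `duals`,
#'   `objective_id`.  Infeasibility is reported in `status`, never
#'   silently zeroed.
#' @export
solve_fba <- function(network, objective_id = network$objective_id,
                      sense = c("max", "min"), loopless = FALSE) {
  sense <- match.arg(sense)
  lp <- .fba_lp(network)
  sol <- .fba_solve_lp(lp, objective_id, sense)
  if (loopless && sol$status == "optimal")
    sol <- enforce_loopless(network, sol)
  sol
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution [", x$status, "]  objective ", x$objective_id, " = ",
      format(x$objective_value, digits = 8), "\n", sep = "")
  nz <- sum(abs(x$fluxes) > 1e-6, na.rm = TRUE)
  cat("  ", nz, "of", length(x$fluxes), "reactions carry flux (>1e-6)\n")
  invisible(x)
}

#' Remove thermodynamically infeasible internal cycles
#'
#' Returns a flux distribution with the same objective value and the
#' same exchange fluxes as `solution` but no net flux around internal
#' (non-exchange) cycles.  The distribution is found by minimising the
#' total absolute internal flux while fixing every exchange flux and the
#' objective flux and restricting each internal reaction to the sign it
#' carries in `solution`; at the minimum no sign-consistent internal
#' cycle can remain, since subtracting it would stay feasible and reduce
#' the total.  Dual values are carried over from the original LP.
#'
#' @param network the network `solution` was solved on.
#' @param solution an optimal `fba_solution`.
#' @return an `fba_solution` with loop-free fluxes and
#'   `loopless = TRUE`.
#' @export
enforce_loopless <- function(network, solution) {
  if (!identical(solution$status, "optimal"))
    stop("enforce_loopless requires an optimal solution")
  lp <- .fba_lp(network)
  v0 <- solution$fluxes[lp$rxn_ids]
  tol <- 1e-9
  lb <- lp$lb; ub <- lp$ub
  internal <- !lp$is_exchange
  obj_j <- match(solution$objective_id, lp$rxn_ids)
  wt <- numeric(length(v0))
  for (j in seq_along(v0)) {
    if (!internal[j] || j == obj_j) {        # pin exchanges and the objective
      lb[j] <- v0[j]; ub[j] <- v0[j]
    } else if (v0[j] > tol) {
      lb[j] <- 0; ub[j] <- v0[j]; wt[j] <- 1
    } else if (v0[j] < -tol) {
      lb[j] <- v0[j]; ub[j] <- 0; wt[j] <- -1
    } else {
      lb[j] <- 0; ub[j] <- 0
    }
  }
  r <- lp_solve(lp$S, lp$b, wt, lb, ub, sense = "min")
  if (r$status != "optimal")
    stop("loop removal LP unexpectedly ", r$status,
         "; the input solution should always be feasible")
  out <- solution
  out$fluxes <- stats::setNames(r$x, lp$rxn_ids)
  out$loopless <- TRUE
  achieved <- out$fluxes[[solution$objective_id]]
  if (abs(achieved - solution$objective_value) > 1e-8)
    stop("loop removal changed the objective by ",
         achieved - solution$objective_value)
  out
}

#' Flux-carrying set
#'
#' The set of reactions with non-zero flux in a solution:
#' `{ r : |v_r| > tol }`.
#'
#' @param solution an optimal `fba_solution`.
#' @param tol flux threshold (default `1e-6`).
#' @return character vector of reaction ids.
#' @export
flux_carrying_set <- function(solution, tol = 1e-6) {
  if (!identical(solution$status, "optimal"))
    stop("flux_carrying_set requires an optimal solution")
  names(solution$fluxes)[abs(solution$fluxes) > tol]
}

#' Classify flux changes between two solutions
#'
#' Compares the flux-carrying sets of a reference and an alternative
#' solution over the same reaction index and classifies every changed
#' reaction as turned on, turned off, increased or decreased.  Shifts
#' are reported as absolute flux-magnitude differences
#' `| |v_alt| - |v_ref| |` with the direction encoded by the group.
#'
#' @param sol_ref,sol_alt optimal `fba_solution`s over the same network.
#' @param tol on/off flux threshold (default `1e-6`).
#' @return an `fcs_diff` with fields `turned_on`, `turned_off`
#'   (character vectors) and `increased`, `decreased` (named numeric
#'   vectors of absolute shifts, sorted decreasing).
#' @export
compare_fcs <- function(sol_ref, sol_alt, tol = 1e-6) {
  if (!identical(names(sol_ref$fluxes), names(sol_alt$fluxes)))
    stop("solutions are over different reaction sets")
  aref <- abs(sol_ref$fluxes); aalt <- abs(sol_alt$fluxes)
  on_ref <- aref > tol; on_alt <- aalt > tol
  shift <- aalt - aref
  turned_on  <- names(aref)[!on_ref & on_alt]
  turned_off <- names(aref)[on_ref & !on_alt]
  both <- on_ref & on_alt
  inc <- both & shift >  tol
  dec <- both & shift < -tol
  increased <- sort(shift[inc], decreasing = TRUE)
  decreased <- sort(abs(shift[dec]), decreasing = TRUE)
  structure(list(turned_on = turned_on, turned_off = turned_off,
                 increased = increased, decreased = decreased, tol = tol),
            class = "fcs_diff")
}

#' @export
print.fcs_diff <- function(x, n = 10, ...) {
  cat("Flux-carrying set changes (tol ", x$tol, ")\n", sep = "")
  cat("  turned on :", length(x$turned_on),
      " turned off:", length(x$turned_off), "\n")
  if (length(x$increased)) {
    cat("  largest increases:\n")
    print(utils::head(round(x$increased, 4), n))
  }
  if (length(x$decreased)) {
    cat("  largest decreases:\n")
    print(utils::head(round(x$decreased, 4), n))
  }
  invisible(x)
}

#' Finite-difference check of metabolite shadow prices
#'
#' Independently estimates each metabolite's sensitivity by re-solving
#' the FBA with a small availability perturbation `eps` on that
#' metabolite's mass balance, from both sides, and compares
#' `-dZ/d(availability)` with the LP dual.  Metabolites whose left and
#' right derivatives differ are degenerate (the dual is not unique
#' there) and are flagged rather than failed.
#'
#' @param network a [metabolic_network()].
#' @param objective_id objective reaction (default: network objective).
#' @param metabolite_ids metabolites to check (default: all).
#' @param eps perturbation size (default `1e-4`).
#' @param tol agreement tolerance on `|fd + lambda|` (default `1e-3`).
#' @return `data.frame` with columns `metabolite`, `lambda_lp`,
#'   `lambda_fd_right`, `lambda_fd_left`, `degenerate`, `agree`.
#' @export
dual_sensitivity_fd <- function(network, objective_id = network$objective_id,
                                metabolite_ids = NULL, eps = 1e-4,
                                tol = 1e-3) {
  lp <- .fba_lp(network)
  if (is.null(metabolite_ids)) metabolite_ids <- lp$met_ids
  base <- .fba_solve_lp(lp, objective_id)
  if (base$status != "optimal") stop("base FBA is ", base$status)
  obj <- .fba_objvec(lp, objective_id)
  res <- lapply(metabolite_ids, function(mid) {
    i <- match(mid, lp$met_ids)
    if (is.na(i)) stop("unknown metabolite: ", mid)
    b2 <- lp$b; b2[i] <- -eps   # availability +eps
    r_plus <- lp_solve(lp$S, b2, obj, lp$lb, lp$ub)
    b2[i] <- eps                # availability -eps
    r_minus <- lp_solve(lp$S, b2, obj, lp$lb, lp$ub)
    zr <- if (r_plus$status == "optimal") r_plus$objective else NA_real_
    zl <- if (r_minus$status == "optimal") r_minus$objective else NA_real_
    lam_r <- -(zr - base$objective_value) / eps
    lam_l <- -(base$objective_value - zl) / eps
    degen <- is.na(lam_r) || is.na(lam_l) || abs(lam_r - lam_l) > tol
    lam <- base$duals[[mid]]
    data.frame(metabolite = mid, lambda_lp = lam,
               lambda_fd_right = lam_r, lambda_fd_left = lam_l,
               degenerate = degen,
               agree = !is.na(lam_r) && abs(lam - lam_r) <= tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Export an FBA solution
#'
#' Writes fluxes as TSV (`reaction`, `flux`) and, optionally, a JSON
#' summary with status, objective and duals.
#'
#' @param solution an `fba_solution`.
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the flux `data.frame`.
#' @export
write_fba_solution <- function(solution, tsv_path = NULL, json_path = NULL) {
  df <- data.frame(reaction = names(solution$fluxes),
                   flux = as.numeric(solution$fluxes))
  if (!is.null(tsv_path))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    js <- jsonlite::toJSON(list(status = solution$status,
                                objective_id = solution$objective_id,
                                objective_value = solution$objective_value,
                                duals = as.list(solution$duals)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(js, json_path)
  }
  invisible(df)
}
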