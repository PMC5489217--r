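# Phenotypic phase plane construction and analysis.
#
# A PhPP scans a 2-D grid of carbon-source and oxygen uptake rates,
# solving at every point the bi-level problem (biomass FBA, then
# ethanol maximisation at fixed biomass) and recording the growth-rate,
# ethanol, yield and ARC-sensitivity surfaces.  Phases are regions of
# constant marginal behaviour; they are detected from quantised
# shadow-price signatures of the two scanned substrates rather than
# from numerical second differences, which is robust to grid
# coarseness.

#' Compute a phenotypic phase plane
#'
#' @param network a [metabolic_network()].
#' @param carbon_exchange_id,o2_exchange_id exchange reactions scanned
#'   along the two axes.
#' @param carbon_axis,o2_axis increasing non-negative uptake-rate grids
#'   (mmol gDW^-1 h^-1).  Defaults: 41 points over 0-20 (carbon) and
#'   0-25 (oxygen).
#' @param secondary_objective_id step-2 objective (default ethanol
#'   exchange).
#' @param compartment compartment whose lambda_ARC fills `arc_surface`
#'   (default cytosol; all compartments are recorded).
#' @param carbon_mw molar mass of the carbon source in g/mol, used for
#'   the g/g yield view (default 150.13, xylose).
#' @param loopless post-process each biomass solution with
#'   [enforce_loopless()] (slower; surfaces are unchanged because the
#'   objective and exchange fluxes are preserved).
#' @param zero_band classification band for the sensitivity class
#'   surface.
#' @return object of class `"phpp_grid"`: surfaces `mu_surface`,
#'   `qetoh_surface`, `yield_surface` (mol/mol), `yield_surface_gg`,
#'   `arc_surface`, `arc_surface_m`, `phase_labels`, `status` (all
#'   carbon x oxygen matrices), the axes, the lines of optimality
#'   `optimality_line_biomass` / `optimality_line_ethanol`, and
#'   `n_phases`.  Infeasible points are recorded in `status` and carry
#'   `NA` surfaces.
#' @export
compute_phpp <- function(network,
                         carbon_exchange_id = "EX_xyl",
                         o2_exchange_id = "EX_o2",
                         carbon_axis = seq(0, 20, length.out = 41),
                         o2_axis = seq(0, 25, length.out = 41),
                         secondary_objective_id = "EX_etoh",
                         compartment = "c",
                         carbon_mw = 150.13,
                         loopless = FALSE,
                         zero_band = 1e-6) {
  stopifnot(length(carbon_axis) > 0, length(o2_axis) > 0,
            !is.unsorted(carbon_axis, strictly = TRUE),
            !is.unsorted(o2_axis, strictly = TRUE),
            all(carbon_axis >= 0), all(o2_axis >= 0))
  # close every other carbon exchange so the scan owns the carbon supply
  for (ex in exchange_ids(network)) {
    rx <- network$reactions[[ex]]
    if (rx$lower_bound < 0 && !(ex %in% c(carbon_exchange_id, o2_exchange_id)))
      network <- set_uptake(network, ex, 0)
  }
  lp0 <- .fba_lp(network)
  jc <- match(carbon_exchange_id, lp0$rxn_ids)
  jo <- match(o2_exchange_id, lp0$rxn_ids)
  if (is.na(jc) || is.na(jo)) stop("exchange id not found in network")
  carbon_met <- names(network$reactions[[carbon_exchange_id]]$stoich)
  o2_met <- names(network$reactions[[o2_exchange_id]]$stoich)
  nc <- length(carbon_axis); no <- length(o2_axis)
  dims <- list(carbon = carbon_axis, o2 = o2_axis)
  mk <- function() matrix(NA_real_, nc, no, dimnames = NULL)
  mu <- qe <- arc_c <- arc_m <- dual_c <- dual_o <- mk()
  status <- matrix("unsolved", nc, no)
  for (i in seq_len(nc)) {
    for (j in seq_len(no)) {
      lp <- lp0
      lp$lb[jc] <- -carbon_axis[i]
      lp$lb[jo] <- -o2_axis[j]
      res <- tryCatch(
        .bilevel_solve(lp, network$objective_id, secondary_objective_id),
        error = function(e) NULL)
      if (is.null(res) || res$step1$status != "optimal") {
        status[i, j] <- if (is.null(res)) "error" else res$step1$status
        next
      }
      status[i, j] <- "optimal"
      mu[i, j] <- res$step1$objective_value
      dual_c[i, j] <- res$step1$duals[[carbon_met]]
      dual_o[i, j] <- res$step1$duals[[o2_met]]
      if (!is.null(res$step2)) {
        qe[i, j] <- res$step2$objective_value
        # networks without NAD(H) pools still get mu/ethanol surfaces
        rec <- tryCatch(arc_sensitivity(res$step2, c("c", "m"), zero_band),
                        error = function(e) NULL)
        if (!is.null(rec)) {
          arc_c[i, j] <- rec$lambda_arc[["c"]]
          arc_m[i, j] <- rec$lambda_arc[["m"]]
        }
      }
      if (loopless) {
        # surfaces depend only on objective and exchange fluxes, which
        # loop removal preserves; running it still guards the contract
        net_ij <- set_uptake(set_uptake(network, carbon_exchange_id,
                                        carbon_axis[i]),
                             o2_exchange_id, o2_axis[j])
        invisible(enforce_loopless(net_ij, res$step1))
      }
    }
  }
  yield <- sweep(qe, 1, carbon_axis, "/")
  yield[!is.finite(yield)] <- 0
  grid <- structure(list(
    carbon_axis = carbon_axis, o2_axis = o2_axis,
    carbon_exchange_id = carbon_exchange_id, o2_exchange_id = o2_exchange_id,
    secondary_objective_id = secondary_objective_id,
    compartment = compartment, carbon_mw = carbon_mw,
    mu_surface = mu, qetoh_surface = qe,
    yield_surface = yield,
    yield_surface_gg = yield * 46.07 / carbon_mw,
    arc_surface = if (compartment == "m") arc_m else arc_c,
    arc_surface_m = arc_m,
    dual_carbon = dual_c, dual_o2 = dual_o,
    status = status, zero_band = zero_band), class = "phpp_grid")
  grid <- detect_phases(grid)
  grid$optimality_line_biomass <- line_of_optimality(grid, "biomass")
  grid$optimality_line_ethanol <- line_of_optimality(grid, "ethanol_yield")
  grid
}

#' @export
print.phpp_grid <- function(x, ...) {
  cat("PhPP grid ", length(x$carbon_axis), "x", length(x$o2_axis),
      " (", x$carbon_exchange_id, " x ", x$o2_exchange_id, ")\n", sep = "")
  cat("  mu range:", paste(signif(range(x$mu_surface, na.rm = TRUE), 4),
                           collapse = " - "), "h^-1\n")
  cat("  phases detected:", x$n_phases, "\n")
  invisible(x)
}

#' Detect phenotypic phases
#'
#' Groups grid points into phases of constant marginal behaviour: two
#' adjacent feasible points share a phase iff their quantised
#' shadow-price signatures (duals of the scanned carbon and oxygen
#' extracellular metabolites, rounded to the quantum) match.  Labels
#' are contiguous positive integers ordered by first occurrence in a
#' row-major scan.
#'
#' @param grid a `phpp_grid`.
#' @param quantum rounding quantum for the dual signature (default
#'   `1e-6`).
#' @return the grid with `phase_labels` (integer matrix; `NA` at
#'   infeasible points) and `n_phases` filled in.
#' @export
detect_phases <- function(grid, quantum = 1e-6) {
  nc <- length(grid$carbon_axis); no <- length(grid$o2_axis)
  sig_c <- round(grid$dual_carbon / quantum)
  sig_o <- round(grid$dual_o2 / quantum)
  labels <- matrix(NA_integer_, nc, no)
  feasible <- grid$status == "optimal"
  next_label <- 0L
  # row-major scan with flood fill over matching-signature neighbours
  for (i in seq_len(nc)) for (j in seq_len(no)) {
    if (!feasible[i, j] || !is.na(labels[i, j])) next
    next_label <- next_label + 1L
    queue <- list(c(i, j))
    labels[i, j] <- next_label
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        a <- p[1] + d[1]; b <- p[2] + d[2]
        if (a < 1 || a > nc || b < 1 || b > no) next
        if (!feasible[a, b] || !is.na(labels[a, b])) next
        if (identical(sig_c[a, b], sig_c[p[1], p[2]]) &&
            identical(sig_o[a, b], sig_o[p[1], p[2]])) {
          labels[a, b] <- next_label
          queue[[length(queue) + 1L]] <- c(a, b)
        }
      }
    }
  }
  grid$phase_labels <- labels
  grid$n_phases <- next_label
  grid
}

#' Line of optimality
#'
#' For `"biomass"`: per carbon-axis value, the smallest oxygen uptake
#' achieving the maximal biomass yield mu / q_carbon (ties resolved
#' toward cheaper oxygen).  For `"ethanol_yield"`: per carbon-axis
#' value, the oxygen uptake maximising the ethanol yield surface
#' (smallest on ties).  Columns that are entirely infeasible are
#' omitted with a message.
#'
#' @param grid a `phpp_grid`.
#' @param quantity `"biomass"` or `"ethanol_yield"`.
#' @param tol tie tolerance on the optimised ratio.
#' @return `data.frame` with `carbon`, `o2`, `i`, `j`, `value` (the
#'   optimal ratio/yield at the point).
#' @export
line_of_optimality <- function(grid, quantity = c("biomass", "ethanol_yield"),
                               tol = 1e-9) {
  quantity <- match.arg(quantity)
  out <- list()
  for (i in seq_along(grid$carbon_axis)) {
    qc <- grid$carbon_axis[i]
    vals <- switch(quantity,
      biomass = if (qc > 0) grid$mu_surface[i, ] / qc else rep(NA_real_,
                                                 length(grid$o2_axis)),
      ethanol_yield = grid$yield_surface[i, ])
    if (all(is.na(vals))) {
      message("line_of_optimality: carbon = ", qc,
              " column entirely infeasible; omitted")
      next
    }
    best <- max(vals, na.rm = TRUE)
    j <- which(!is.na(vals) & vals >= best - tol)[1]
    out[[length(out) + 1L]] <- data.frame(
      carbon = qc, o2 = grid$o2_axis[j], i = i, j = j, value = best)
  }
  do.call(rbind, out)
}

#' Export a PhPP grid
#'
#' Writes one TSV per surface plus a JSON manifest with the axes and
#' configuration.
#'
#' @param grid a `phpp_grid`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the manifest list.
#' @export
write_phpp <- function(grid, dir, prefix = "phpp") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surfaces <- c("mu_surface", "qetoh_surface", "yield_surface",
                "yield_surface_gg", "arc_surface", "phase_labels")
  files <- character()
  for (s in surfaces) {
    f <- file.path(dir, paste0(prefix, "_", s, ".tsv"))
    m <- grid[[s]]
    df <- data.frame(carbon = rep(grid$carbon_axis, times = ncol(m)),
                     o2 = rep(grid$o2_axis, each = nrow(m)),
                     value = as.vector(m))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[s] <- basename(f)
  }
  manifest <- list(carbon_axis = grid$carbon_axis, o2_axis = grid$o2_axis,
                   carbon_exchange_id = grid$carbon_exchange_id,
                   o2_exchange_id = grid$o2_exchange_id,
                   compartment = grid$compartment,
                   n_phases = grid$n_phases, files = as.list(files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, paste0(prefix, "_manifest.json")))
  invisible(manifest)
}

#' Heat-map view of a PhPP surface
#'
#' Simple image rendering of one surface with the biomass (black) and
#' ethanol-yield (blue) lines of optimality overlaid.
#'
#' @param x a `phpp_grid`.
#' @param surface surface name (default `"mu_surface"`).
#' @param ... passed to [graphics::image()].
#' @return invisibly, `NULL`.
#' @export
plot.phpp_grid <- function(x, surface = "mu_surface", ...) {
  m <- x[[surface]]
  graphics::image(x$carbon_axis, x$o2_axis, m,
                  xlab = paste0(x$carbon_exchange_id, " uptake"),
                  ylab = paste0(x$o2_exchange_id, " uptake"),
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = surface, ...)
  lb <- x$optimality_line_biomass
  if (!is.null(lb)) graphics::lines(lb$carbon, lb$o2, lty = 2, lwd = 2)
  le <- x$optimality_line_ethanol
  if (!is.null(le)) graphics::lines(le$carbon, le$o2, lty = 2, lwd = 2,
                                    col = "blue")
  invisible(NULL)
}

#' Count grid cells by ARC sensitivity class
#'
#' @param grid a `phpp_grid`.
#' @param zero_band classification band (defaults to the grid's).
#' @return named integer vector with counts `limiting` (< 0), `excess`
#'   (> 0) and `no_effect`.
#' @export
arc_region_counts <- function(grid, zero_band = grid$zero_band) {
  a <- grid$arc_surface
  c(limiting = sum(a < -zero_band, na.rm = TRUE),
    no_effect = sum(abs(a) <= zero_band, na.rm = TRUE),
    excess = sum(a > zero_band, na.rm = TRUE))
}
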