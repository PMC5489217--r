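# Metabolic network data model and constraint editing.
#
# A network is a plain S3 list: a metabolite table, an ordered list of
# reactions (each with a named stoichiometry vector and flux bounds), and
# the id of the objective reaction.  All editing operations return a
# modified copy; nothing mutates in place, so grid scans and trajectory
# loops are side-effect free.

#' Create a metabolite
#'
#' @param id unique short identifier.
#' @param name free-text name.
#' @param compartment compartment code (e.g. `"c"` cytosol, `"m"`
#'   mitochondrion, `"e"` extracellular).
#' @param carbon number of carbon atoms (used for elemental bookkeeping
#'   checks on lumped reactions; `NA` to opt out).
#' @return a one-row `data.frame`.
#' @export
metabolite <- function(id, name = id, compartment, carbon = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  data.frame(id = id, name = name, compartment = compartment,
             carbon = carbon, stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative for substrates,
#' positive for products.  Flux bounds are in mmol per gram dry weight per
#' hour; by the usual constraint-based convention a negative exchange flux
#' is uptake and a positive one secretion.
#'
#' @param id unique short identifier.
#' @param stoich named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound flux bounds (mmol gDW^-1 h^-1).
#' @param name free-text name.
#' @param is_exchange is this a boundary exchange reaction?
#' @param subsystem free-text pathway label.
#' @return an object of class `"fba_reaction"`.
#' @export
reaction <- function(id, stoich, lower_bound = 0, upper_bound = 1000,
                     name = id, is_exchange = FALSE, subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  structure(list(id = id, name = name, stoich = stoich,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 is_exchange = isTRUE(is_exchange), subsystem = subsystem),
            class = "fba_reaction")
}

#' Assemble a metabolic network
#'
#' @param metabolites `data.frame` with columns `id`, `name`,
#'   `compartment` (and optionally `carbon`), e.g. built by row-binding
#'   [metabolite()] calls.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the objective reaction (typically biomass).
#' @param compartments declared compartment codes; defaults to those used.
#' @return object of class `"metabolic_network"`.
#' @export
metabolic_network <- function(metabolites, reactions, objective_id,
                              compartments = NULL) {
  if (is.null(metabolites$carbon)) metabolites$carbon <- NA_real_
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        objective_id = objective_id,
                        compartments = compartments),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks id uniqueness, compartment membership, stoichiometry resolution,
#' bound ordering, the exchange-reaction contract (exactly one metabolite)
#' and that the objective id resolves.
#'
#' @param network a `metabolic_network`.
#' @return the network, invisibly; errors describe the offending element.
#' @export
validate_network <- function(network) {
  met <- network$metabolites
  if (anyDuplicated(met$id))
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (!all(met$compartment %in% network$compartments))
    stop("metabolite compartments outside the declared set: ",
         paste(setdiff(met$compartment, network$compartments), collapse = ", "))
  rids <- vapply(network$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (rx in network$reactions) {
    unknown <- setdiff(names(rx$stoich), met$id)
    if (length(unknown))
      stop("reaction '", rx$id, "' references unknown metabolites: ",
           paste(unknown, collapse = ", "))
    if (rx$lower_bound > rx$upper_bound)
      stop("reaction '", rx$id, "': lower_bound > upper_bound")
    if (rx$is_exchange && length(rx$stoich) != 1L)
      stop("exchange reaction '", rx$id,
           "' must touch exactly one metabolite")
  }
  if (!network$objective_id %in% rids)
    stop("objective_id '", network$objective_id,
         "' does not resolve to a reaction")
  invisible(network)
}

#' Stoichiometric matrix view
#'
#' @param network a `metabolic_network`.
#' @return dense m x n matrix `S` with metabolite ids as row names and
#'   reaction ids as column names; `S v = 0` is the steady-state system.
#' @export
stoich_matrix <- function(network) {
  mids <- network$metabolites$id
  rids <- vapply(network$reactions, `[[`, "", "id")
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Flux bounds of every reaction
#'
#' @param network a `metabolic_network`.
#' @return `data.frame` with `id`, `lower_bound`, `upper_bound`.
#' @export
reaction_bounds <- function(network) {
  data.frame(
    id = vapply(network$reactions, `[[`, "", "id"),
    lower_bound = vapply(network$reactions, `[[`, 0, "lower_bound"),
    upper_bound = vapply(network$reactions, `[[`, 0, "upper_bound"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Ids of exchange reactions
#' @param network a `metabolic_network`.
#' @return character vector.
#' @export
exchange_ids <- function(network) {
  names(Filter(function(r) r$is_exchange, network$reactions))
}

.get_reaction <- function(network, id) {
  rx <- network$reactions[[id]]
  if (is.null(rx)) stop("unknown reaction id: ", id)
  rx
}

#' Constrain the uptake rate through an exchange reaction
#'
#' Sets the exchange lower bound to `-rate`, so the network may take up at
#' most `rate` mmol gDW^-1 h^-1 of the metabolite (uptake = negative
#' exchange flux).  Secretion through the same exchange stays permitted.
#'
#' @param network a `metabolic_network`.
#' @param exchange_id id of an exchange reaction.
#' @param rate maximal uptake rate, non-negative.
#' @return a modified copy of the network.
#' @export
set_uptake <- function(network, exchange_id, rate) {
  rx <- .get_reaction(network, exchange_id)
  if (!rx$is_exchange)
    stop("'", exchange_id, "' is not an exchange reaction")
  if (!is.finite(rate) || rate < 0)
    stop("uptake rate must be non-negative, got ", rate)
  rx$lower_bound <- -rate
  if (rx$upper_bound < rx$lower_bound) rx$upper_bound <- rx$lower_bound
  network$reactions[[exchange_id]] <- rx
  network
}

#' Knock out reactions
#'
#' Sets both flux bounds of each listed reaction to zero.
#'
#' @param network a `metabolic_network`.
#' @param reaction_ids character vector of reaction ids (may be empty).
#' @return a modified copy of the network.
#' @export
knockout <- function(network, reaction_ids) {
  unknown <- setdiff(reaction_ids, names(network$reactions))
  if (length(unknown))
    stop("unknown reaction ids: ", paste(unknown, collapse = ", "))
  for (id in reaction_ids) {
    network$reactions[[id]]$lower_bound <- 0
    network$reactions[[id]]$upper_bound <- 0
  }
  network
}

#' Partially inhibit a reaction
#'
#' Caps the flux magnitude at `(1 - fraction) * reference_flux`.  The
#' model reads an enzymatic inhibition as a bound cap relative to a
#' reference state, usually the reaction's flux in the uninhibited optimum
#' under the same uptake constraints (which the caller supplies).
#' `fraction = 1` reproduces a knockout; `fraction = 0` with the reference
#' equal to the current optimal flux is non-binding.
#'
#' @param network a `metabolic_network`.
#' @param reaction_id reaction to inhibit.
#' @param fraction inhibited fraction in `[0, 1]` (0.8 = "inhibited by 80%").
#' @param reference_flux non-negative reference flux magnitude.
#' @return a modified copy of the network.
#' @export
inhibit <- function(network, reaction_id, fraction, reference_flux) {
  rx <- .get_reaction(network, reaction_id)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("inhibition fraction must lie in [0, 1], got ", fraction)
  if (!is.finite(reference_flux) || reference_flux < 0)
    stop("reference_flux must be non-negative")
  cap <- (1 - fraction) * reference_flux
  rx$upper_bound <- min(rx$upper_bound, cap)
  if (rx$lower_bound < 0) rx$lower_bound <- max(rx$lower_bound, -cap)
  network$reactions[[reaction_id]] <- rx
  network
}

#' Summarise a network as JSON
#'
#' @param network a `metabolic_network`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when written to file).
#' @export
network_summary_json <- function(network, path = NULL) {
  bd <- reaction_bounds(network)
  out <- list(
    n_metabolites = nrow(network$metabolites),
    n_reactions = length(network$reactions),
    compartments = network$compartments,
    objective_id = network$objective_id,
    metabolites = network$metabolites$id,
    reactions = bd)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  cat("  objective:", x$objective_id, "\n")
  invisible(x)
}

#' Per-reaction carbon balance
#'
#' For every reaction whose metabolites all carry a declared carbon count,
#' reports the signed carbon sum (substrate carbon in, product carbon
#' out).  Reactions listed in `exempt` (by default the biomass/objective
#' reaction, whose product is a lumped pseudo-species) are skipped.
#'
#' @param network a `metabolic_network`.
#' @param exempt reaction ids excluded from the check.
#' @return named numeric vector of carbon imbalances (0 = balanced).
#' @export
carbon_balance <- function(network, exempt = character()) {
  carb <- stats::setNames(network$metabolites$carbon, network$metabolites$id)
  res <- c()
  for (rx in network$reactions) {
    if (rx$id %in% exempt || rx$is_exchange) next
    ci <- carb[names(rx$stoich)]
    if (any(is.na(ci))) next
    res[rx$id] <- sum(rx$stoich * ci)
  }
  res
}
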