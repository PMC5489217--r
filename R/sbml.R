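# SBML input/output.
#
# Writes SBML Level 3 Version 1 with the fbc (version 2) extension:
# flux bounds as global constant parameters referenced from
# fbc:lowerFluxBound / fbc:upperFluxBound, the objective as an fbc
# objective, and subsystem / carbon annotations in notes.  The reader
# accepts the same layout plus two legacy bound encodings (kineticLaw
# LOWER_BOUND/UPPER_BOUND parameters and "LOWER_BOUND: x" lines in
# reaction notes).

.sbml_num <- function(x)
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE), "")

#' Write a network as SBML Level 3 + fbc
#'
#' @param network a [metabolic_network()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_sbml <- function(network, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="core_model" fbc:strict="false">',
    '    <listOfCompartments>')
  for (cp in network$compartments)
    L <- c(L, sprintf('      <compartment id="%s" constant="true"/>', cp))
  L <- c(L, '    </listOfCompartments>', '    <listOfSpecies>')
  for (k in seq_len(nrow(network$metabolites))) {
    mt <- network$metabolites[k, ]
    notes <- if (!is.na(mt$carbon)) paste0(
      '><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>CARBON: ',
      .sbml_num(mt$carbon), '</p></body></notes></species>') else '/>'
    L <- c(L, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s'),
      mt$id, esc(mt$name), mt$compartment, notes))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfParameters>')
  bd <- reaction_bounds(network)
  vals <- sort(unique(c(bd$lower_bound, bd$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)), .sbml_num(vals))
  for (v in vals)
    L <- c(L, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      pid[[.sbml_num(v)]], .sbml_num(v)))
  L <- c(L, '    </listOfParameters>', '    <listOfReactions>')
  for (rx in network$reactions) {
    L <- c(L, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      rx$id, esc(rx$name), tolower(rx$lower_bound < 0),
      pid[[.sbml_num(rx$lower_bound)]], pid[[.sbml_num(rx$upper_bound)]]))
    L <- c(L, sprintf(
      paste0('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
             '<p>SUBSYSTEM: %s</p><p>EXCHANGE: %s</p></body></notes>'),
      esc(rx$subsystem), rx$is_exchange))
    subs <- rx$stoich[rx$stoich < 0]; prods <- rx$stoich[rx$stoich > 0]
    if (length(subs)) {
      L <- c(L, '        <listOfReactants>')
      for (mi in names(subs))
        L <- c(L, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          mi, .sbml_num(-subs[[mi]])))
      L <- c(L, '        </listOfReactants>')
    }
    if (length(prods)) {
      L <- c(L, '        <listOfProducts>')
      for (mi in names(prods))
        L <- c(L, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          mi, .sbml_num(prods[[mi]])))
      L <- c(L, '        </listOfProducts>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            network$objective_id),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>', '</sbml>')
  writeLines(L, path)
  invisible(path)
}

.strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

.attr_by_localname <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", local, "$"), names(at))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

.notes_field <- function(node, key) {
  txt <- xml2::xml_text(xml2::xml_find_all(
    node, ".//*[local-name()='notes']//*[local-name()='p']"))
  hit <- grep(paste0("^", key, ":"), txt, value = TRUE)
  if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1]))
  else NA_character_
}

#' Read an SBML model
#'
#' Accepts SBML Level 2 or 3; flux bounds are taken from fbc bound
#' parameters when present, else from kineticLaw `LOWER_BOUND` /
#' `UPPER_BOUND` parameters, else from `LOWER_BOUND: x` note lines,
#' else default to (-1000, 1000) for reversible and (0, 1000) for
#' irreversible reactions.  `M_` / `R_` id prefixes are stripped.
#'
#' @param path SBML file.
#' @param objective_id optional objective reaction id, overriding (or
#'   supplying, when the file lacks an fbc objective) the active
#'   objective.
#' @return a [metabolic_network()].
#' @export
load_sbml <- function(path, objective_id = NULL) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot parse SBML file '", path, "': ", conditionMessage(e)))
  find <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  comp_nodes <- find(doc, "compartment")
  compartments <- vapply(comp_nodes, function(n) .attr_by_localname(n, "id"), "")
  if (!length(compartments))
    stop("SBML error in ", path, ": no listOfCompartments/compartment")
  sp_nodes <- find(doc, "species")
  if (!length(sp_nodes))
    stop("SBML error in ", path, ": no species elements")
  mets <- do.call(rbind, lapply(sp_nodes, function(n) {
    id <- .strip_prefix(.attr_by_localname(n, "id"), "M_")
    nm <- .attr_by_localname(n, "name")
    carbon <- suppressWarnings(as.numeric(.notes_field(n, "CARBON")))
    metabolite(id, if (is.na(nm)) id else nm,
               .attr_by_localname(n, "compartment"), carbon)
  }))
  # fbc bound parameters
  par_nodes <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(par_nodes, function(n)
      suppressWarnings(as.numeric(.attr_by_localname(n, "value"))), 0),
    vapply(par_nodes, function(n) .attr_by_localname(n, "id"), ""))
  rx_nodes <- find(doc, "reaction")
  if (!length(rx_nodes))
    stop("SBML error in ", path, ": no reaction elements")
  reactions <- lapply(rx_nodes, function(n) {
    rid <- .strip_prefix(.attr_by_localname(n, "id"), "R_")
    nm <- .attr_by_localname(n, "name")
    rev <- identical(.attr_by_localname(n, "reversible"), "true")
    stoich <- c()
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(n, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (r in refs) {
        sp <- .strip_prefix(.attr_by_localname(r, "species"), "M_")
        st <- suppressWarnings(as.numeric(.attr_by_localname(r, "stoichiometry")))
        if (is.na(st)) st <- 1
        stoich[sp] <- (if (sp %in% names(stoich)) stoich[[sp]] else 0) + sgn * st
      }
    }
    if (!length(stoich))
      stop("SBML error in ", path, ": reaction '", rid,
           "' has no reactants or products")
    lb_id <- .attr_by_localname(n, "lowerFluxBound")
    ub_id <- .attr_by_localname(n, "upperFluxBound")
    lb <- if (!is.na(lb_id) && lb_id %in% names(par_val)) par_val[[lb_id]]
          else NA_real_
    ub <- if (!is.na(ub_id) && ub_id %in% names(par_val)) par_val[[ub_id]]
          else NA_real_
    if (is.na(lb) || is.na(ub)) {
      kl <- xml2::xml_find_all(n, paste0(
        ".//*[local-name()='kineticLaw']//*[local-name()='parameter']",
        " | .//*[local-name()='kineticLaw']//*[local-name()='localParameter']"))
      for (p in kl) {
        pid <- .attr_by_localname(p, "id")
        pv <- suppressWarnings(as.numeric(.attr_by_localname(p, "value")))
        if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- pv
        if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- pv
      }
    }
    if (is.na(lb)) {
      nb <- suppressWarnings(as.numeric(.notes_field(n, "LOWER_BOUND")))
      if (!is.na(nb)) lb <- nb
    }
    if (is.na(ub)) {
      nb <- suppressWarnings(as.numeric(.notes_field(n, "UPPER_BOUND")))
      if (!is.na(nb)) ub <- nb
    }
    if (is.na(lb)) lb <- if (rev) -1000 else 0
    if (is.na(ub)) ub <- 1000
    subsystem <- .notes_field(n, "SUBSYSTEM")
    exch_note <- .notes_field(n, "EXCHANGE")
    is_exch <- if (!is.na(exch_note)) identical(tolower(exch_note), "true")
               else (length(stoich) == 1L || grepl("^EX_", rid))
    reaction(rid, stoich, lb, ub, name = if (is.na(nm)) rid else nm,
             is_exchange = is_exch,
             subsystem = if (is.na(subsystem)) "" else subsystem)
  })
  if (is.null(objective_id)) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (inherits(fo, "xml_missing"))
      stop("SBML file '", path, "' declares no objective; ",
           "call load_sbml(path, objective_id = \"<reaction id>\")")
    objective_id <- .strip_prefix(.attr_by_localname(fo, "reaction"), "R_")
  }
  metabolic_network(mets, reactions, objective_id,
                    compartments = compartments)
}
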