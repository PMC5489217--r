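test_that("SBML round trip is lossless for the generated network", {
  net <- toy_net()
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, tf)
  net2 <- load_sbml(tf)
  expect_equal(net2$metabolites$id, net$metabolites$id)
  expect_equal(net2$metabolites$compartment, net$metabolites$compartment)
  expect_equal(net2$metabolites$carbon, net$metabolites$carbon)
  expect_equal(names(net2$reactions), names(net$reactions))
  expect_equal(reaction_bounds(net2), reaction_bounds(net))
  expect_identical(net2$objective_id, net$objective_id)
  for (id in names(net$reactions)) {
    a <- net$reactions[[id]]; b <- net2$reactions[[id]]
    expect_equal(sort(names(b$stoich)), sort(names(a$stoich)), info = id)
    expect_equal(b$stoich[sort(names(b$stoich))],
                 a$stoich[sort(names(a$stoich))], info = id)
    expect_identical(b$is_exchange, a$is_exchange, info = id)
    expect_identical(b$subsystem, a$subsystem, info = id)
  }
  # and the reloaded model solves identically
  mu1 <- solve_fba(with_uptakes(net, 10, 40))$objective_value
  mu2 <- solve_fba(with_uptakes(net2, 10, 40))$objective_value
  expect_equal(mu2, mu1, tolerance = 1e-12)
})

test_that("written bounds survive: an exchange with (-10, 1000) reloads exactly", {
  net <- set_uptake(toy_net(), "EX_xyl", 10)
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, tf)
  net2 <- load_sbml(tf)
  expect_equal(net2$reactions$EX_xyl$lower_bound, -10)
  expect_equal(net2$reactions$EX_xyl$upper_bound, 1000)
})

test_that("reader errors are specific", {
  expect_error(load_sbml("no/such/file.xml"), "not found")
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml>", tf)
  expect_error(load_sbml(tf), "cannot parse")
  # objective missing: instruct the caller
  tf2 <- withr::local_tempfile(fileext = ".xml")
  txt <- readLines(write_sbml(toy_net(), tf2))
  txt <- txt[!grepl("fbc:listOfObjectives|fbc:objective|fluxObjective", txt)]
  writeLines(txt, tf2)
  expect_error(load_sbml(tf2), "objective_id")
  expect_identical(load_sbml(tf2, objective_id = "BIOMASS")$objective_id,
                   "BIOMASS")
})

test_that("legacy note-encoded bounds are honoured", {
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="legacy">',
    '<listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a_e" compartment="e"/>',
    '<species id="M_a_c" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_EX_a" reversible="true">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>LOWER_BOUND: -7.5</p><p>UPPER_BOUND: 42</p></body></notes>',
    '<listOfReactants><speciesReference species="M_a_e"/></listOfReactants>',
    '</reaction>',
    '<reaction id="R_t" reversible="false">',
    '<listOfReactants><speciesReference species="M_a_e"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_a_c" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'), tf)
  net <- load_sbml(tf, objective_id = "t")
  expect_equal(net$reactions$EX_a$lower_bound, -7.5)
  expect_equal(net$reactions$EX_a$upper_bound, 42)
  expect_true(net$reactions$EX_a$is_exchange)
  expect_equal(net$reactions$t$lower_bound, 0)     # irreversible default
  expect_equal(net$reactions$t$stoich[["a_c"]], 2)
})

test_that("an independent SBML implementation reads the written file", {
  # cobra (Python) as external oracle for format validity
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy_net(), tf)
  out <- tryCatch(system2("python", c("-c", shQuote(sprintf(
    "import cobra; m = cobra.io.read_sbml_model('%s'); print(len(m.reactions), len(m.metabolites))",
    tf))), stdout = TRUE, stderr = FALSE), error = function(e) NULL)
  expect_false(is.null(out))
  counts <- as.integer(strsplit(out[length(out)], " ")[[1]])
  expect_equal(counts, c(length(toy_net()$reactions),
                         nrow(toy_net()$metabolites)))
})
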