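Package: arcfba
Title: Redox-Cofactor Sensitivity Analysis of Flux Balance Models with
    Batch-Culture Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constraint-based analysis of core metabolic networks centred on
    the response of growth and ethanol production to the available reducing
    capacity (ARC) of the NAD(H) redox pair in xylose-fermenting yeast.
    Provides a flux balance analysis (FBA) engine with metabolite shadow
    prices, loop-removing post-processing, flux-carrying-set comparison,
    phenotypic phase plane (PhPP) construction with phase detection and lines
    of optimality, ARC sensitivity indices for biomass and ethanol objectives,
    respiratory-chain knockout and partial-inhibition simulation, a
    Monod/Luedeking-Piret batch-culture model with least-squares parameter
    estimation, and coupling of culture rate trajectories back into FBA to
    obtain sensitivity trajectories. Includes a synthetic core network
    generator and synthetic batch-culture data sets so the full workflow is
    testable without external model files. Reads and writes SBML Level 3 with
    the 'fbc' extension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
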