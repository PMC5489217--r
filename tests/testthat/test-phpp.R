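# PhPP geometry on an 11 x 11 toy grid (fast) with spot checks against
# standalone solves; finer grids are exercised by the acceptance tests.

phpp_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- compute_phpp(toy_net(),
                             carbon_axis = seq(0, 20, length.out = 11),
                             o2_axis = seq(0, 25, length.out = 11))
    cache
  }
})

test_that("axes must be increasing and non-negative", {
  expect_error(compute_phpp(toy_net(), carbon_axis = c(5, 1),
                            o2_axis = c(0, 1)))
  expect_error(compute_phpp(toy_net(), carbon_axis = c(-1, 1),
                            o2_axis = c(0, 1)))
})

test_that("growth surface: zero-carbon column, monotonicity and concavity", {
  g <- phpp_small()
  expect_true(all(g$mu_surface[1, ] == 0))
  expect_true(all(g$status == "optimal"))
  # monotone along both axes
  expect_true(all(apply(g$mu_surface, 1, function(r) all(diff(r) >= -1e-8))))
  expect_true(all(apply(g$mu_surface, 2, function(cc) all(diff(cc) >= -1e-8))))
  # concave along each axis-aligned section (midpoint test)
  for (i in seq_len(nrow(g$mu_surface))) {
    r <- g$mu_surface[i, ]
    expect_true(all(r[-c(1, length(r))] >=
                    (r[-c(length(r) - 1, length(r))] + r[-c(1, 2)]) / 2 - 1e-8))
  }
  for (j in seq_len(ncol(g$mu_surface))) {
    cc <- g$mu_surface[, j]
    expect_true(all(cc[-c(1, length(cc))] >=
                    (cc[-c(length(cc) - 1, length(cc))] + cc[-c(1, 2)]) / 2 - 1e-8))
  }
})

test_that("yield bookkeeping: yield x carbon uptake reproduces ethanol flux", {
  g <- phpp_small()
  for (i in seq_along(g$carbon_axis)) {
    qc <- g$carbon_axis[i]
    expect_equal(g$yield_surface[i, ] * qc,
                 if (qc > 0) g$qetoh_surface[i, ] else rep(0, ncol(g$qetoh_surface)),
                 tolerance = 1e-8)
  }
  expect_equal(g$yield_surface_gg, g$yield_surface * 46.07 / 150.13)
})

test_that("grid points agree with fresh standalone solves", {
  g <- phpp_small()
  set.seed(33)
  for (k in 1:10) {
    i <- sample(seq_along(g$carbon_axis), 1)
    j <- sample(seq_along(g$o2_axis), 1)
    sol <- solve_fba(with_uptakes(toy_net(), g$carbon_axis[i], g$o2_axis[j]))
    expect_equal(g$mu_surface[i, j], sol$objective_value, tolerance = 1e-9)
  }
})

test_that("ethanol is absent strictly right of the biomass line of optimality", {
  g <- phpp_small()
  line <- g$optimality_line_biomass
  for (r in seq_len(nrow(line))) {
    i <- line$i[r]
    right <- g$o2_axis > line$o2[r] + 1e-9
    if (any(right))
      expect_true(all(g$qetoh_surface[i, right] <= 1e-6),
                  info = paste("carbon =", line$carbon[r]))
  }
})

test_that("the biomass line is a fixed-proportion ray through the origin", {
  line <- phpp_small()$optimality_line_biomass
  # while the stoichiometric oxygen demand (1.742 per mmol xylose) fits
  # inside the scanned oxygen range, the maximal biomass yield is the
  # aerobic constant; beyond it the ray leaves the grid
  inside <- line$carbon > 0 & line$carbon * 1.7422 <= max(phpp_small()$o2_axis)
  expect_gt(sum(inside), 3)
  expect_true(all(abs(line$value[inside] - TOY_MU_PER_XYL) < 1e-9))
  # the optimal oxygen grid point grows with carbon (grid-resolution ray)
  expect_true(all(diff(line$o2) >= 0))
})

test_that("the ethanol-yield line lies left (lower oxygen) of the biomass line", {
  g <- phpp_small()
  lb <- g$optimality_line_biomass
  le <- g$optimality_line_ethanol
  shared <- intersect(lb$carbon, le$carbon)
  shared <- shared[shared > 0]
  o_b <- lb$o2[match(shared, lb$carbon)]
  o_e <- le$o2[match(shared, le$carbon)]
  expect_true(all(o_e <= o_b))
  expect_true(any(o_e < o_b))
})

test_that("at least three phases partition the toy plane", {
  g <- phpp_small()
  expect_gte(g$n_phases, 3)
  labs <- g$phase_labels
  expect_true(all(!is.na(labs)))
  expect_setequal(unique(as.vector(labs)), seq_len(g$n_phases))
})

test_that("growth is locally linear inside each detected phase", {
  # phases are constant-derivative regions: away from phase boundaries
  # the second difference of mu vanishes
  g <- phpp_small()
  labs <- g$phase_labels
  mu <- g$mu_surface
  nc <- nrow(mu); no <- ncol(mu)
  checked <- 0L
  for (i in 2:(nc - 1)) for (j in 2:(no - 1)) {
    same <- labs[i, j] == labs[i - 1, j] && labs[i, j] == labs[i + 1, j] &&
            labs[i, j] == labs[i, j - 1] && labs[i, j] == labs[i, j + 1]
    if (!same) next
    d2c <- mu[i - 1, j] - 2 * mu[i, j] + mu[i + 1, j]
    d2o <- mu[i, j - 1] - 2 * mu[i, j] + mu[i, j + 1]
    expect_lt(abs(d2c), 1e-6); expect_lt(abs(d2o), 1e-6)
    checked <- checked + 1L
  }
  expect_gt(checked, 10L)
})

test_that("a linear one-substrate network yields a single phase with edge lines", {
  g <- compute_phpp(single_phase_network(),
                    carbon_exchange_id = "EX_A", o2_exchange_id = "EX_O",
                    carbon_axis = seq(0, 10, length.out = 6),
                    o2_axis = seq(0, 10, length.out = 6))
  expect_identical(g$n_phases, 1L)
  expect_equal(g$mu_surface, matrix(rep(g$carbon_axis, 6), 6, 6),
               tolerance = 1e-9)
  # both lines of optimality collapse onto the cheap-oxygen grid edge
  expect_true(all(g$optimality_line_biomass$o2 == 0))
  expect_true(all(g$optimality_line_ethanol$o2 == 0))
})

test_that("grid export writes every surface plus a manifest", {
  dir <- withr::local_tempdir()
  man <- write_phpp(phpp_small(), dir)
  expect_true(file.exists(file.path(dir, "phpp_manifest.json")))
  for (f in unlist(man$files)) expect_true(file.exists(file.path(dir, f)))
  tsv <- utils::read.table(file.path(dir, "phpp_mu_surface.tsv"),
                           header = TRUE, sep = "\t")
  expect_equal(nrow(tsv), 11 * 11)
})
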