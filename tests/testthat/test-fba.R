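test_that("FBA solves hand-checkable toy problems", {
  chain <- make_toy_model("chain")
  res <- fba_optimize(chain)
  expect_equal(res$status, "optimal")
  expect_equal(res$objective_value, 10)            # uptake-limited single path
  expect_equal(unname(res$fluxes[c("EX_a", "T_a", "biomass")]),
               c(-10, 10, 10))

  closed <- set_bounds(chain, "EX_a", lower_bound = 0)
  expect_equal(fba_optimize(closed)$objective_value, 0)

  # producible-but-unconsumable metabolite with forced production
  bad <- metabolic_model(
    list(metabolite("x_c")),
    list(reaction("make_x", c(x_c = 1), lower_bound = 1, upper_bound = 10),
         reaction("other", c(x_c = 1), lower_bound = 0, upper_bound = 0)),
    "other")
  expect_equal(fba_optimize(bad, "make_x")$status, "infeasible")
})

test_that("optimal solutions satisfy steady state and bounds", {
  for (seed in 1:25) {
    net <- random_network(seed)
    res <- fba_optimize(net$model)
    expect_equal(res$status, "optimal")
    S <- as.matrix(stoichiometric_matrix(net$model))
    expect_lt(max(abs(S %*% res$fluxes)), 1e-6)
    expect_true(all(res$fluxes >= net$lb - 1e-9))
    expect_true(all(res$fluxes <= net$ub + 1e-9))
  }
  applied <- apply_medium(make_toy_model("amino_sugar_core"),
                          bundled_media()$glcnac)
  res <- fba_optimize(applied)
  S <- as.matrix(stoichiometric_matrix(applied))
  expect_lt(max(abs(S %*% res$fluxes)), 1e-6)
})

test_that("FBA agrees with the scipy HiGHS oracle on random networks", {
  nets <- lapply(101:130, random_network)
  oracle <- oracle_linprog(nets)
  for (k in seq_along(nets)) {
    res <- fba_optimize(nets[[k]]$model)
    expect_equal(res$status, oracle[[k]]$status)
    if (res$status == "optimal") {
      expect_lt(abs(res$objective_value - oracle[[k]]$obj) /
                  max(1, abs(oracle[[k]]$obj)), 1e-6)
    }
  }
})

test_that("FVA ranges behave as derived on fixture networks", {
  # unique flux distribution: every range collapses to a point
  fva <- flux_variability(make_toy_model("chain"))
  expect_equal(fva$min_flux, fva$max_flux, tolerance = 1e-7)

  # redundant parallel routes of capacity 10: each spans [0, 10]
  fva <- flux_variability(make_toy_model("parallel"))
  r1 <- fva[fva$reaction_id == "route1", ]
  expect_equal(c(r1$min_flux, r1$max_flux), c(0, 10), tolerance = 1e-7)
  r2 <- fva[fva$reaction_id == "route2", ]
  expect_equal(c(r2$min_flux, r2$max_flux), c(0, 10), tolerance = 1e-7)

  # disconnected reaction pinned at zero bounds: range [0, 0]
  m <- make_toy_model("chain")
  m$metabolites[["z_c"]] <- metabolite("z_c")
  m$reactions[["dead"]] <- reaction("dead", c(z_c = 1), lower_bound = 0,
                                    upper_bound = 0)
  fva <- flux_variability(m)
  dead <- fva[fva$reaction_id == "dead", ]
  expect_equal(c(dead$min_flux, dead$max_flux), c(0, 0))

  expect_error(flux_variability(set_bounds(make_toy_model("chain"), "EX_a",
                                           lower_bound = 0, upper_bound = 0),
                                fraction_of_optimum = 1),
               NA) # zero optimum is still a valid base problem
})

test_that("FVA sandwich: FBA flux lies within every FVA range", {
  for (seed in c(7, 21, 35)) {
    net <- random_network(seed)
    res <- fba_optimize(net$model)
    fva <- flux_variability(net$model, net$model$objective_id)
    expect_true(all(fva$min_flux <= res$fluxes + 1e-6))
    expect_true(all(res$fluxes <= fva$max_flux + 1e-6))
    expect_true(all(fva$min_flux <= fva$max_flux + 1e-9))
  }
})

test_that("knockouts zero bounds, preserve redundancy, and are idempotent", {
  chain <- make_toy_model("chain")
  ko <- knockout(chain, "biomass")
  expect_equal(fba_optimize(ko)$objective_value, 0)
  expect_equal(chain$reactions[["biomass"]]$upper_bound, 1000) # source intact

  par <- make_toy_model("parallel")
  expect_equal(fba_optimize(knockout(par, "route1"))$objective_value,
               fba_optimize(par)$objective_value)

  twice <- knockout(knockout(chain, "T_a"), "T_a")
  expect_true(structurally_equal(twice, knockout(chain, "T_a")))
  expect_error(knockout(chain, "nope"), "unknown reaction")
})

test_that("optimum is monotone non-decreasing in the uptake bound", {
  chain <- make_toy_model("chain")
  mus <- vapply(seq(0, 12, by = 1.5), function(b) {
    fba_optimize(set_bounds(chain, "EX_a", lower_bound = -b))$objective_value
  }, 0)
  expect_true(all(diff(mus) >= -1e-9))

  bott <- make_toy_model("bottleneck")
  mus <- vapply(c(0, 3, 7, 9, 12), function(b) {
    fba_optimize(set_bounds(bott, "EX_a", lower_bound = -b))$objective_value
  }, 0)
  expect_equal(mus, c(0, 3, 7, 7, 7))   # saturates at the internal cap
})

test_that("cobrapy reads our SBML and reproduces the FBA optimum", {
  applied <- apply_medium(make_toy_model("amino_sugar_core"),
                          bundled_media()$glcnac_glucose)
  p <- tempfile(fileext = ".xml")
  write_model(applied, p, "sbml")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import cobra.io",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "print('%.8f' % m.optimize().objective_value)"), script)
  out <- suppressWarnings(system2("python", c(script, p), stdout = TRUE,
                                  stderr = FALSE))
  val <- suppressWarnings(as.numeric(out[length(out)]))
  expect_false(is.na(val))
  expect_equal(val, fba_optimize(applied)$objective_value, tolerance = 1e-6)
})
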