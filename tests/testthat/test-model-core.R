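test_that("toy models satisfy counts, exchange flagging and S structure", {
  m <- make_toy_model("chain")
  expect_length(m$reactions, 3)
  expect_length(m$metabolites, 2)
  expect_true(m$reactions[["EX_a"]]$is_exchange)
  expect_false(m$reactions[["T_a"]]$is_exchange)
  is_ex <- vapply(m$reactions, `[[`, TRUE, "is_exchange")
  n_touched <- vapply(m$reactions, function(r) length(r$stoichiometry), 0L)
  expect_equal(is_ex, n_touched == 1L)

  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(as.numeric(S["a_e", "T_a"]), -1)
  expect_equal(as.numeric(S["a_c", "T_a"]), 1)
  expect_equal(as.numeric(S["a_e", "EX_a"]), -1)

  empty <- metabolic_model(list(), list(), "biomass", id = "empty")
  expect_equal(dim(stoichiometric_matrix(empty)), c(0L, 0L))
})

test_that("model invariants are enforced", {
  a <- metabolite("a_c")
  expect_error(metabolic_model(list(a), list(reaction("r", c(b_c = 1))),
                               "r"), "undeclared metabolite")
  expect_error(reaction("r", c(a_c = -1), lower_bound = 5, upper_bound = 1),
               "lower_bound > upper_bound")
  expect_error(reaction("r", numeric()), "non-empty")
  expect_error(metabolic_model(list(a), list(reaction("r", c(a_c = 1))),
                               "missing_objective"), "objective")
})

test_that("equation grammar round-trips stoichiometries", {
  cases <- list(
    c(a_c = -2, b_c = -1, c_c = 1),
    c(x_c = -1),
    c(p_c = 1, q_c = 0.5, s_c = -1.25))
  for (st in cases) {
    eq <- mucimin:::format_equation(st)
    parsed <- mucimin:::parse_equation(eq)
    expect_equal(parsed$stoichiometry[order(names(parsed$stoichiometry))],
                 st[order(names(st))])
  }
  rev <- mucimin:::parse_equation("a_c <=> b_c")
  expect_true(rev$reversible)
  expect_error(mucimin:::parse_equation("a_c b_c"), "arrow")
})

test_that("SBML and table round-trips preserve structure", {
  for (kind in c("chain", "parallel", "amino_sugar_core")) {
    m <- make_toy_model(kind)
    sb <- tempfile(fileext = ".xml")
    write_model(m, sb, "sbml")
    expect_true(structurally_equal(m, read_model(sb, "sbml")))
    tb <- tempfile()
    write_model(m, tb, "table")
    expect_true(structurally_equal(m, read_model(tb, "table")))
  }
})

test_that("reading rejects malformed input and duplicate ids refuse to write", {
  p <- tempfile(fileext = ".xml")
  writeLines("this is not xml <", p)
  expect_error(read_model(p, "sbml"), "parse failure")
  expect_error(read_model(tempfile(), "table"), "not found")

  # SBML reaction referencing an undeclared species
  bad <- tempfile(fileext = ".xml")
  writeLines(c(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="bad"><listOfSpecies>',
    '<species id="M_a_c" compartment="c" boundaryCondition="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_biomass" reversible="false">',
    '<listOfReactants><speciesReference species="M_ghost_c" stoichiometry="1"/>',
    '</listOfReactants></reaction>',
    '</listOfReactions></model></sbml>'), bad)
  expect_error(read_model(bad, "sbml"), "undeclared metabolite")

  m <- make_toy_model("chain")
  m$reactions <- c(m$reactions, m$reactions["T_a"])  # tampered duplicate
  expect_error(write_model(m, tempfile(), "table"), "duplicate")
})

test_that("a Level 3 fbc model is read with fbc bounds and objective", {
  p <- tempfile(fileext = ".xml")
  writeLines(c(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1">',
    '<model id="l3toy">',
    '<listOfCompartments><compartment id="c" constant="true"/>',
    '<compartment id="e" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a_e" compartment="e" boundaryCondition="false"/>',
    '<species id="M_a_c" compartment="c" boundaryCondition="false"/>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lb_m10" value="-10" constant="true"/>',
    '<parameter id="lb_0" value="0" constant="true"/>',
    '<parameter id="ub_1000" value="1000" constant="true"/>',
    '</listOfParameters>',
    '<listOfReactions>',
    '<reaction id="R_EX_a" reversible="true" fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_1000">',
    '<listOfReactants><speciesReference species="M_a_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '<reaction id="R_T_a" reversible="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">',
    '<listOfReactants><speciesReference species="M_a_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_a_c" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_grow" reversible="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">',
    '<listOfReactants><speciesReference species="M_a_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives>',
    '<fbc:fluxObjective fbc:reaction="R_grow" fbc:coefficient="1"/>',
    '</fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
    '</model></sbml>'), p)
  m <- read_model(p, "sbml")
  expect_equal(m$objective_id, "grow")
  expect_equal(m$reactions[["EX_a"]]$lower_bound, -10)
  expect_equal(fba_optimize(m)$objective_value, 10)
})

test_that("curation steps apply, refuse invalid edits, and log replays", {
  v1 <- make_toy_model("amino_sugar_core", with_glms = TRUE)

  cur <- apply_curation(v1, list())
  expect_true(structurally_equal(cur$model, v1))
  expect_length(cur$log, 0)

  steps <- read_curation(system.file("extdata", "curation", "v1_to_v2.json",
                                     package = "mucimin"))
  cur <- apply_curation(v1, steps)
  expect_false("GLMS" %in% names(cur$model$reactions))
  expect_true("GLMS" %in% names(v1$reactions))  # source unmodified
  v2 <- make_toy_model("amino_sugar_core")
  expect_true(structurally_equal(prune_unused_metabolites(cur$model), v2))

  # replaying the recorded log reproduces the target
  replay <- apply_curation(v1, lapply(cur$log, function(e) e$step))
  expect_true(structurally_equal(replay$model, cur$model))

  expect_error(apply_curation(v1, list(curation_step("remove_reaction",
                                                     "NOPE"))), "absent")
  expect_error(apply_curation(v1, list(curation_step("add_reaction",
    list(id = "GLYC", equation = "a_c --> b_c")))), "duplicate")

  # adding a reversible epimerase to a core stripped of it
  stripped <- apply_curation(v2, list(curation_step("remove_reaction",
                                                    "UDPEPI")))$model
  added <- apply_curation(stripped, list(curation_step("add_reaction",
    list(id = "UDPEPI", equation = "udpglcnac_c <=> udpgalnac_c",
         lower_bound = -1000, upper_bound = 1000))))$model
  expect_length(added$reactions, length(stripped$reactions) + 1)
  expect_lt(added$reactions[["UDPEPI"]]$lower_bound, 0)
})

test_that("diff and apply are dual on perturbed model pairs", {
  base <- make_toy_model("amino_sugar_core")
  expect_length(diff_models(base, base), 0)

  minus <- apply_curation(base, list(curation_step("remove_reaction",
                                                   "PPAS")))$model
  d <- diff_models(base, minus)
  expect_length(d, 1)
  expect_equal(d[[1]]$kind, "remove_reaction")

  set.seed(42)
  for (k in 1:10) {
    a <- base
    b <- base
    # random bound change, removal, and addition
    rid <- sample(names(b$reactions), 1)
    b <- set_bounds(b, rid, upper_bound = b$reactions[[rid]]$upper_bound / 2)
    drop <- sample(setdiff(names(b$reactions), c(rid, "biomass")), 1)
    b$reactions[[drop]] <- NULL
    b$reactions[["extra"]] <- reaction("extra", c(atp_c = -1, ac_c = 1))
    res <- apply_curation(a, diff_models(a, b))
    expect_true(structurally_equal(res$model, b))
  }
})
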