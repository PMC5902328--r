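core_v2 <- make_toy_model("amino_sugar_core")
core_v1 <- make_toy_model("amino_sugar_core", with_glms = TRUE)
media <- bundled_media()

test_that("apply_medium translates categories into exchange bounds", {
  m <- apply_medium(core_v2, media$glucose)
  bd <- reaction_bounds(m)
  bnd <- function(id) bd[bd$id == id, ]
  expect_equal(bnd("EX_glc")$lower_bound, -10)      # sole sugar gets the budget
  expect_equal(bnd("EX_glcnac")$lower_bound, 0)     # non-medium uptake closed
  expect_equal(bnd("EX_thr")$lower_bound, -1)       # threonine capped at 1
  expect_equal(bnd("EX_nh4")$lower_bound, -1000)    # non-limiting
  expect_equal(bnd("EX_ac")$lower_bound, 0)         # secretion only
  expect_true(all(bd[grepl("^EX_", bd$id), "upper_bound"] == 1000))

  two <- apply_medium(core_v2, media$glcnac_glucose)
  bd2 <- reaction_bounds(two)
  expect_equal(bd2[bd2$id == "EX_glcnac", "lower_bound"], -5)  # equimolar split
  expect_equal(bd2[bd2$id == "EX_glc", "lower_bound"], -5)

  empty <- medium_spec("empty", list())
  closed <- apply_medium(core_v2, empty)
  bd3 <- reaction_bounds(closed)
  expect_true(all(bd3[grepl("^EX_", bd3$id), "lower_bound"] == 0))
  expect_equal(fba_optimize(closed)$objective_value, 0)
})

test_that("apply_medium is idempotent, order-independent, and errors on missing exchanges", {
  once <- apply_medium(core_v2, media$glcnac)
  expect_true(structurally_equal(apply_medium(once, media$glcnac), once))

  shuffled <- media$glcnac
  set.seed(1)
  shuffled$components <- sample(shuffled$components)
  expect_true(structurally_equal(apply_medium(core_v2, shuffled), once))

  orphan <- medium_spec("orphan", list(
    medium_component("accoa_c", "non_limiting")))
  expect_error(apply_medium(core_v2, orphan),
               "no exchange reaction.*accoa_c")
  # predict_growth converts the same failure into a structured no-route row
  p <- predict_growth(core_v2, orphan)
  expect_false(p$grows)
  expect_equal(p$mu_au, 0)
  expect_match(p$note, "accoa_c")
})

test_that("the growth table reproduces the in vitro / in silico comparison pattern", {
  gt <- growth_table(list(v1 = core_v1, v2 = core_v2), media)
  expect_equal(gt$medium, c("glucose_glcn", "glcn", "glcnac",
                            "glcnac_glucose", "galnac", "glucose"))
  expect_equal(gt$v2_grows, c("n", "n", "y", "y", "y", "n"))
  expect_equal(gt$v1_grows, c("y", "n", "y", "y", "y", "y"))
  # growing predictions are well above threshold; mixture beats single sugar
  expect_true(all(gt$v2_au[gt$v2_grows == "y"] > 1))
  au <- setNames(gt$v2_au, gt$medium)
  expect_gt(au[["glcnac_glucose"]], au[["glcnac"]])
  expect_equal(au[["glcnac"]], au[["galnac"]], tolerance = 1e-9)

  expect_equal(nrow(growth_table(list(v2 = core_v2), list())), 0)
})

test_that("the hypothetical GlcN transporter is the sole block on GlcN media", {
  core_t <- make_toy_model("amino_sugar_core", with_glcn_transporter = TRUE)
  expect_false(predict_growth(core_v2, media$glcn)$grows)
  expect_false(predict_growth(core_v2, media$glucose_glcn)$grows)
  expect_true(predict_growth(core_t, media$glcn)$grows)
  expect_true(predict_growth(core_t, media$glucose_glcn)$grows)
})

test_that("essentiality scan flags threonine and amino sugars correctly", {
  es <- essentiality_scan(core_v2, media$glcnac)
  row <- function(d, id) d[d$metabolite_id == id, ]
  expect_true(row(es, "thr_e")$essential)            # threonine omission: no growth
  expect_true(row(es, "glcnac_e")$essential)         # sole amino sugar
  expect_false(row(es, "h2o_e")$essential)           # unused trace component
  base_mu <- predict_growth(core_v2, media$glcnac)$mu_au
  expect_equal(row(es, "h2o_e")$mu_without, base_mu, tolerance = 1e-9)

  # with GalNAc present, GlcNAc is no longer essential
  both <- medium_spec("both", c(media$glcnac$components,
                                list(medium_component("galnac_e", "sugar"))))
  es2 <- essentiality_scan(core_v2, both)
  expect_false(row(es2, "glcnac_e")$essential)
  expect_false(row(es2, "galnac_e")$essential)

  expect_error(essentiality_scan(core_v2, media$glucose), "does not support")
})

test_that("uptake scans are monotone and saturate at internal bottlenecks", {
  sc <- uptake_scan(core_v2, media$glcnac, "glcnac_e", grid = c(0, 2, 5, 10))
  expect_equal(sc$mu_au[1], 0)
  expect_true(all(diff(sc$mu_au) >= -1e-9))
  # linear regime: mu proportional to the bound
  expect_equal(sc$mu_au[-1] / sc$bound[-1],
               rep(sc$mu_au[4] / 10, 3), tolerance = 1e-6)

  # second bottleneck: cap GlcNAc phosphorylation at 7
  capped <- set_bounds(core_v2, "GLCNACt", upper_bound = 7)
  sc2 <- uptake_scan(capped, media$glcnac, "glcnac_e", grid = c(0, 5, 7, 8, 10))
  expect_equal(sc2$mu_au[4], sc2$mu_au[3], tolerance = 1e-9)
  expect_equal(sc2$mu_au[5], sc2$mu_au[3], tolerance = 1e-9)

  expect_error(uptake_scan(core_v2, media$glcnac, "glc_e"), "unknown sugar")
})

test_that("flux-distribution comparison classifies substrate shifts", {
  cmp <- compare_flux_distributions(core_v2,
                                    list(media$glcnac, media$glcnac_glucose))
  cls <- setNames(cmp$glcnac_glucose_class, cmp$reaction_id)
  # the deacetylation route carries less flux when glucose covers energy needs
  expect_equal(cls[["DEAC"]], "lower")
  expect_equal(cls[["NAGB"]], "lower")
  # glucose uptake appears only in the mixture
  expect_equal(cls[["GLCt"]], "higher")
  # fructose exchange carries no flux under either medium
  expect_equal(cls[["EX_fru"]], "similar")

  same <- media$glcnac
  same$name <- "again"
  cmp2 <- compare_flux_distributions(core_v2, list(media$glcnac, same))
  expect_true(all(cmp2$again_class == "similar"))
})

test_that("media serialize to JSON and back", {
  p <- tempfile(fileext = ".json")
  write_medium(media$glcnac_glucose, p)
  back <- read_medium(p)
  expect_equal(back$name, media$glcnac_glucose$name)
  expect_equal(back$sugar_budget, 10)
  expect_equal(length(back$components), length(media$glcnac_glucose$components))
  expect_true(structurally_equal(apply_medium(core_v2, back),
                                 apply_medium(core_v2, media$glcnac_glucose)))
})
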