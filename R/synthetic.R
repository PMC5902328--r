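#' Simulation configuration
#'
#' Bundles the seed and noise settings shared by the synthetic-data
#' generators. Every generator is a pure function of its parameters and
#' the seed: the global RNG state is saved and restored around each call,
#' and a fixed seed reproduces the output bit for bit.
#'
#' @param seed Integer seed.
#' @param noise_cv Noise coefficient of variation (fraction, e.g. 0.05).
#' @param n_replicates Number of replicates to generate.
#' @param grid Sampling grid (times in h for curves and fermentations,
#'   concentrations in mM for assays); `NULL` uses each generator's
#'   default.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, noise_cv = 0, n_replicates = 3L,
                       grid = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L, noise_cv >= 0,
            n_replicates >= 1)
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates), grid = grid),
            class = "SimConfig")
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Multiplicative log-normal noise with unit mean: positivity-preserving,
# CV = cv.
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Toy metabolic networks
#'
#' Small networks with known LP optima, used as fixtures throughout:
#' \describe{
#'   \item{`chain`}{uptake -> conversion -> biomass; the optimum equals the
#'     uptake bound.}
#'   \item{`parallel`}{two redundant routes of capacity 10 feeding biomass,
#'     so FVA ranges span `[0, 10]` for each route.}
#'   \item{`bottleneck`}{a chain whose internal conversion is capped at 7,
#'     so growth saturates there.}
#'   \item{`amino_sugar_core`}{the amino-sugar core of A. muciniphila
#'     metabolism: exchanges for glucose, fructose, GlcNAc, GalNAc, GlcN,
#'     L-threonine, acetate, propionate, ammonium (plus inert water and
#'     phosphate); lumped glycolysis of Fru6P to acetyl-CoA, ATP and NADH;
#'     acetate (ATP-yielding) and propionate (NADH-reoxidizing) secretion
#'     branches; NagB as the irreversible GlcN6P -> Fru6P + NH4
#'     deamination; direct GlcNAc uptake/phosphorylation to GlcNAc6P (the
#'     GlcNAc shortcut); deacetylase GlcNAc6P -> GlcN6P + acetate;
#'     acetyltransferase GlcN6P + acetyl-CoA -> GlcNAc6P; reversible
#'     UDP-GlcNAc synthesis from GlcNAc6P and the reversible UDP-GlcNAc
#'     <-> UDP-GalNAc 4-epimerase; GalNAc entry via the UDP route; biomass
#'     requiring UDP-GlcNAc, threonine and ATP. `with_glms` adds the
#'     glutamine-dependent Fru6P amination (the reaction wrongly
#'     gap-filled into model v1) plus a glutamine-regenerating synthetase;
#'     `with_glcn_transporter` adds the hypothetical GlcN
#'     uptake/phosphorylation route. Without GlmS, growth requires an
#'     exogenous amino sugar — the glms-mutant phenotype.}
#' }
#'
#' @param kind Network kind (see above).
#' @param with_glms,with_glcn_transporter Flags, meaningful for
#'   `amino_sugar_core` only.
#' @param yields Named list overriding the core's fixture coefficients:
#'   `glyc_atp` (3), `glyc_nadh` (2), `glyc_accoa` (2), `ppa_atp` (2),
#'   `ppa_n` (2), `biomass_udpglcnac` (1), `biomass_thr` (0.1),
#'   `biomass_atp` (5). The defaults make the acetate:propionate yield
#'   2:1 on pure GlcNAc and lower on GlcNAc/glucose mixtures.
#' @return A validated `MetabolicModel` (version_tag `"toy"`, or
#'   `"v1-like"` / `"v2-like"` for the amino-sugar core with/without
#'   GlmS).
#' @export
make_toy_model <- function(kind = c("chain", "parallel", "bottleneck",
                                    "amino_sugar_core"),
                           with_glms = FALSE, with_glcn_transporter = FALSE,
                           yields = list()) {
  kind <- match.arg(kind)
  if (kind != "amino_sugar_core" && (with_glms || with_glcn_transporter)) {
    stop("with_glms / with_glcn_transporter are only meaningful for ",
         "kind = 'amino_sugar_core'")
  }
  ext <- function(id, name = id) metabolite(id, name, "extracellular")
  cyt <- function(id, name = id) metabolite(id, name, "cytosol")
  ex <- function(met) reaction(paste0("EX_", sub("_e$", "", met)),
                               stats::setNames(-1, met),
                               lower_bound = 0, upper_bound = 1000)
  if (kind == "chain") {
    return(metabolic_model(
      list(ext("a_e"), cyt("a_c")),
      list(reaction("EX_a", c(a_e = -1), lower_bound = -10),
           reaction("T_a", c(a_e = -1, a_c = 1)),
           reaction("biomass", c(a_c = -1))),
      "biomass", version_tag = "toy", id = "toy_chain"))
  }
  if (kind == "parallel") {
    return(metabolic_model(
      list(ext("a_e"), cyt("b_c")),
      list(reaction("EX_a", c(a_e = -1), lower_bound = -10),
           reaction("route1", c(a_e = -1, b_c = 1), upper_bound = 10),
           reaction("route2", c(a_e = -1, b_c = 1), upper_bound = 10),
           reaction("biomass", c(b_c = -1))),
      "biomass", version_tag = "toy", id = "toy_parallel"))
  }
  if (kind == "bottleneck") {
    return(metabolic_model(
      list(ext("a_e"), cyt("a_c"), cyt("b_c")),
      list(reaction("EX_a", c(a_e = -1), lower_bound = -10),
           reaction("T_a", c(a_e = -1, a_c = 1)),
           reaction("conv", c(a_c = -1, b_c = 1), upper_bound = 7),
           reaction("biomass", c(b_c = -1))),
      "biomass", version_tag = "toy", id = "toy_bottleneck"))
  }
  # amino_sugar_core
  yd <- utils::modifyList(list(glyc_atp = 3, glyc_nadh = 2, glyc_accoa = 2,
                               ppa_atp = 2, ppa_n = 2,
                               biomass_udpglcnac = 1, biomass_thr = 0.1,
                               biomass_atp = 5), yields)
  mets <- list(
    ext("glc_e", "glucose"), ext("fru_e", "fructose"),
    ext("glcnac_e", "N-acetylglucosamine"),
    ext("galnac_e", "N-acetylgalactosamine"),
    ext("glcn_e", "glucosamine"), ext("thr_e", "L-threonine"),
    ext("ac_e", "acetate"), ext("ppa_e", "propionate"),
    ext("nh4_e", "ammonium"), ext("h2o_e", "water"),
    ext("pi_e", "phosphate"),
    cyt("fru6p_c", "fructose-6-phosphate"),
    cyt("glcn6p_c", "glucosamine-6-phosphate"),
    cyt("glcnac6p_c", "N-acetylglucosamine-6-phosphate"),
    cyt("udpglcnac_c", "UDP-N-acetylglucosamine"),
    cyt("udpgalnac_c", "UDP-N-acetylgalactosamine"),
    cyt("accoa_c", "acetyl-CoA"), cyt("atp_c", "ATP equivalent"),
    cyt("nadh_c", "NADH equivalent"),
    cyt("ac_c", "acetate"), cyt("ppa_c", "propionate"),
    cyt("nh4_c", "ammonium"), cyt("thr_c", "L-threonine"))
  rxns <- list(
    ex("glc_e"), ex("fru_e"), ex("glcnac_e"), ex("galnac_e"), ex("glcn_e"),
    ex("thr_e"), ex("ac_e"), ex("ppa_e"), ex("nh4_e"), ex("h2o_e"),
    ex("pi_e"),
    reaction("GLCt", c(glc_e = -1, fru6p_c = 1),
             name = "glucose uptake and isomerization"),
    reaction("FRUt", c(fru_e = -1, fru6p_c = 1),
             name = "fructose uptake and phosphorylation"),
    reaction("GLCNACt", c(glcnac_e = -1, atp_c = -1, glcnac6p_c = 1),
             name = "GlcNAc uptake and phosphorylation (GlcNAc shortcut)"),
    reaction("GALNACt", c(galnac_e = -1, atp_c = -2, udpgalnac_c = 1),
             name = "GalNAc entry via the UDP route"),
    reaction("THRt", c(thr_e = -1, thr_c = 1), name = "threonine uptake"),
    reaction("ACt", c(ac_c = -1, ac_e = 1), name = "acetate secretion"),
    reaction("PPAt", c(ppa_c = -1, ppa_e = 1), name = "propionate secretion"),
    reaction("NH4t", c(nh4_c = -1, nh4_e = 1), lower_bound = -1000,
             name = "ammonium transport (reversible)"),
    reaction("GLYC", stats::setNames(
      c(-1, yd$glyc_accoa, yd$glyc_atp, yd$glyc_nadh),
      c("fru6p_c", "accoa_c", "atp_c", "nadh_c")),
      name = "lumped glycolysis to acetyl-CoA"),
    reaction("ACK", c(accoa_c = -1, ac_c = 1, atp_c = 1),
             name = "acetate branch (acetate kinase)"),
    reaction("PPAS", stats::setNames(
      c(-1, -yd$ppa_n, yd$ppa_n, yd$ppa_atp),
      c("fru6p_c", "nadh_c", "ppa_c", "atp_c")),
      name = "propionate branch (NADH-reoxidizing succinate route)"),
    reaction("NAGB", c(glcn6p_c = -1, fru6p_c = 1, nh4_c = 1),
             name = "glucosamine-6-phosphate deaminase (deaminating only)",
             annotation = "EC 3.5.99.6"),
    reaction("DEAC", c(glcnac6p_c = -1, glcn6p_c = 1, ac_c = 1),
             name = "GlcNAc6P deacetylase", annotation = "EC 3.5.1.25"),
    reaction("ACTR", c(glcn6p_c = -1, accoa_c = -1, glcnac6p_c = 1),
             name = "GlcN6P N-acetyltransferase"),
    reaction("UDPGNAC_S", c(glcnac6p_c = -1, atp_c = -1, udpglcnac_c = 1),
             lower_bound = -1000,
             name = "UDP-GlcNAc synthesis (reversible)"),
    reaction("UDPEPI", c(udpglcnac_c = -1, udpgalnac_c = 1),
             lower_bound = -1000,
             name = "UDP-GlcNAc 4-epimerase (reversible)",
             annotation = "locus Amuc_1125"),
    reaction("ATPM", c(atp_c = -1), name = "ATP maintenance sink"),
    reaction("biomass", stats::setNames(
      c(-yd$biomass_udpglcnac, -yd$biomass_thr, -yd$biomass_atp),
      c("udpglcnac_c", "thr_c", "atp_c")),
      name = "biomass synthesis"))
  if (with_glms) {
    mets <- c(mets, list(cyt("gln_c", "L-glutamine"),
                         cyt("glu_c", "L-glutamate")))
    rxns <- c(rxns, list(
      reaction("GLMS", c(fru6p_c = -1, gln_c = -1, glcn6p_c = 1, glu_c = 1),
               name = "glutamine-fructose-6-phosphate transaminase",
               annotation = "EC 2.6.1.16"),
      reaction("GLNS", c(glu_c = -1, nh4_c = -1, atp_c = -1, gln_c = 1),
               name = "glutamine synthetase (amino-donor recycling)")))
  }
  if (with_glcn_transporter) {
    rxns <- c(rxns, list(
      reaction("GLCNt", c(glcn_e = -1, atp_c = -1, glcn6p_c = 1),
               name = "hypothetical GlcN uptake and phosphorylation")))
  }
  metabolic_model(mets, rxns, "biomass",
                  version_tag = if (with_glms) "v1-like" else "v2-like",
                  id = "amino_sugar_core")
}

#' Simulate OD600 growth curves
#'
#' Logistic-capped exponential growth sampled on a time grid with
#' multiplicative log-normal noise (unit mean, CV `noise_cv`):
#' `OD(t) = cap / (1 + (cap/od0 - 1) exp(-mu t))`, which is exponential at
#' rate `mu` while `OD << cap` and saturates at `cap` (stationary phase).
#' `mu = 0` gives a flat curve at `od0` plus noise.
#'
#' @param mu Specific growth rate (h^-1, >= 0).
#' @param od0 Initial OD600 (0 < `od0` < `cap_od`).
#' @param cap_od Stationary-phase OD600 cap.
#' @param config A [sim_config()]; `grid` defaults to
#'   `seq(0, 60, by = 2)` h.
#' @return List of `config$n_replicates` [growth_curve()] objects.
#' @export
simulate_growth_curve <- function(mu, od0 = 0.02, cap_od = 0.5,
                                  config = sim_config()) {
  stopifnot(mu >= 0, od0 > 0, od0 < cap_od)
  times <- if (is.null(config$grid)) seq(0, 60, by = 2) else config$grid
  mean_od <- cap_od / (1 + (cap_od / od0 - 1) * exp(-mu * times))
  with_seed(config$seed, {
    lapply(seq_len(config$n_replicates), function(r) {
      growth_curve(times, mean_od * lnoise(length(times), config$noise_cv),
                   replicate_id = r,
                   condition = sprintf("mu=%g", mu))
    })
  })
}

#' Simulate a fermentation time series
#'
#' Sugars are consumed linearly at the given rates until depletion; each
#' consumed mM of a sugar yields the given mM of acetate and propionate
#' (fixed yield stoichiometry, so e.g. acetate:propionate 1:1 or 1:2
#' outcomes are set by the yields). Additive Gaussian noise (SD =
#' `noise_cv` times the analyte's final scale) is applied and floored at
#' 0.
#'
#' @param sugars Named numeric vector of initial concentrations (mM).
#' @param acid_yields Named list: sugar -> `c(acetate = ..., propionate =
#'   ...)` yields per mM consumed.
#' @param consumption_rates Named numeric vector of consumption rates
#'   (mM/h), same names as `sugars`.
#' @param config A [sim_config()]; `grid` defaults to
#'   `seq(0, 48, by = 4)` h.
#' @return A [metabolite_timeseries()] with one column per sugar plus
#'   `acetate` and `propionate`.
#' @export
simulate_fermentation <- function(sugars, acid_yields, consumption_rates,
                                  config = sim_config()) {
  stopifnot(all(sugars >= 0), all(consumption_rates >= 0),
            setequal(names(sugars), names(consumption_rates)))
  times <- if (is.null(config$grid)) seq(0, 48, by = 4) else config$grid
  conc <- list()
  ac <- numeric(length(times)); pr <- numeric(length(times))
  for (sg in names(sugars)) {
    level <- pmax(0, sugars[[sg]] - consumption_rates[[sg]] * times)
    consumed <- sugars[[sg]] - level
    conc[[sg]] <- level
    yl <- acid_yields[[sg]]
    if (is.null(yl)) yl <- c(acetate = 0, propionate = 0)
    stopifnot(all(yl >= 0))
    ac <- ac + yl[["acetate"]] * consumed
    pr <- pr + yl[["propionate"]] * consumed
  }
  conc$acetate <- ac; conc$propionate <- pr
  with_seed(config$seed, {
    noisy <- lapply(conc, function(x) {
      scale <- max(x, 1e-12)
      pmax(0, x + stats::rnorm(length(x), sd = config$noise_cv * scale))
    })
    metabolite_timeseries(times, noisy,
                          condition = paste(names(sugars), collapse = "+"))
  })
}

#' Simulate enzyme-assay initial rates
#'
#' Michaelis-Menten rates `v = Vmax [S] / (Km + [S])` at the given
#' concentrations with multiplicative log-normal noise (unit mean, CV
#' `noise_cv`), one [assay_series()] per replicate.
#'
#' @param Km Michaelis constant (mM, > 0).
#' @param Vmax Maximal rate (> 0).
#' @param concentrations Substrate concentrations (mM); default 8 points
#'   log-spaced from `0.1 * Km` to `10 * Km`.
#' @param config A [sim_config()].
#' @param substrate_id Substrate label.
#' @param activator_conc Activator concentration label (mM).
#' @return List of `config$n_replicates` `AssaySeries`.
#' @export
simulate_assay <- function(Km, Vmax, concentrations = NULL,
                           config = sim_config(), substrate_id = "S",
                           activator_conc = 0) {
  stopifnot(Km > 0, Vmax > 0)
  if (is.null(concentrations)) {
    concentrations <- if (is.null(config$grid))
      exp(seq(log(0.1 * Km), log(10 * Km), length.out = 8)) else config$grid
  }
  v <- Vmax * concentrations / (Km + concentrations)
  with_seed(config$seed, {
    lapply(seq_len(config$n_replicates), function(r) {
      assay_series(substrate_id, concentrations,
                   v * lnoise(length(v), config$noise_cv),
                   replicate_id = r, activator_conc = activator_conc)
    })
  })
}

#' Write a complete synthetic fixture dataset
#'
#' Emits, under `dir`: the amino-sugar core models (`core_v1`/`core_v2`
#' SBML + tables), the six bundled media (JSON), triplicate growth curves
#' for the growth-rate conditions (CSV), fermentation series for the
#' three yield scenarios (CSV), and enzyme assays at the three NagB
#' substrate ground truths (CSV). Everything is derived from `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(make_toy_model("amino_sugar_core", with_glms = TRUE),
              file.path(dir, "core_v1.xml"), "sbml")
  write_model(make_toy_model("amino_sugar_core"),
              file.path(dir, "core_v2.xml"), "sbml")
  write_model(make_toy_model("amino_sugar_core"),
              file.path(dir, "core_v2"), "table")
  for (nm in names(bundled_media())) {
    write_medium(bundled_media()[[nm]], file.path(dir, paste0(nm, ".json")))
  }
  mu_truth <- c(glcnac_glc = 0.122, glcnac = 0.056, galnac = 0.084,
                glcn_glc = 0.005, glc = 0)
  curves <- list()
  for (k in seq_along(mu_truth)) {
    cs <- simulate_growth_curve(mu_truth[[k]],
      config = sim_config(seed + k, noise_cv = 0.03, n_replicates = 3))
    curves <- c(curves, lapply(cs, function(cu) {
      cu$condition <- names(mu_truth)[k]; cu
    }))
  }
  write_growth_curves(curves, file.path(dir, "growth_curves.csv"))
  ferments <- list(
    simulate_fermentation(c(glcnac = 12.5, glucose = 12.5),
      list(glcnac = c(acetate = 1, propionate = 1),
           glucose = c(acetate = 1, propionate = 1)),
      c(glcnac = 0.5, glucose = 0.5),
      sim_config(seed + 11, noise_cv = 0.02)),
    simulate_fermentation(c(glcnac = 25),
      list(glcnac = c(acetate = 2, propionate = 1)),
      c(glcnac = 0.8), sim_config(seed + 12, noise_cv = 0.02)),
    simulate_fermentation(c(glucose = 12.5, glcn = 5),
      list(glucose = c(acetate = 0.5, propionate = 1),
           glcn = c(acetate = 0, propionate = 0)),
      c(glucose = 0.4, glcn = 0.1), sim_config(seed + 13, noise_cv = 0.02)))
  write_hplc(ferments, file.path(dir, "fermentation.csv"))
  km_truth <- c(Fru6P = 5.5, NH4 = 41.3, GlcN6P = 2.4)
  assays <- list()
  for (k in seq_along(km_truth)) {
    assays <- c(assays, simulate_assay(km_truth[[k]], Vmax = 2,
      config = sim_config(seed + 20 + k, noise_cv = 0.05, n_replicates = 3),
      substrate_id = names(km_truth)[k]))
  }
  write_assays(assays, file.path(dir, "assays.csv"))
  invisible(dir)
}
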