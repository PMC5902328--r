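#' Medium component
#'
#' One metabolite of a medium recipe together with its bound category,
#' following the simulation conventions of the A. muciniphila model:
#' \describe{
#'   \item{`non_limiting`}{abundant medium components (water, phosphate,
#'     trace metals, ...): exchange lower bound set to -1000 a.u.}
#'   \item{`limited_uptake`}{components supplied at a capped uptake rate
#'     (threonine is supplemented with a maximal uptake of 1 a.u.):
#'     lower bound `-uptake_bound`.}
#'   \item{`sugar`}{carbon sources sharing the medium's sugar budget
#'     equally (equimolar mixtures): lower bound `-(sugar_budget / number
#'     of sugars)`.}
#'   \item{`secretion_only`}{present in the recipe but never taken up
#'     (fermentation products): lower bound 0.}
#' }
#' Secretion is always allowed: every exchange upper bound is 1000 a.u.
#'
#' @param metabolite_id Metabolite id resolved against the model's
#'   exchange reactions.
#' @param category One of the four categories above.
#' @param uptake_bound Non-negative uptake cap (a.u.), used for
#'   `limited_uptake` only.
#' @return An object of class `MediumComponent`.
#' @export
medium_component <- function(metabolite_id,
                             category = c("non_limiting", "limited_uptake",
                                          "sugar", "secretion_only"),
                             uptake_bound = NA_real_) {
  category <- match.arg(category)
  if (category == "limited_uptake") {
    stopifnot(is.finite(uptake_bound), uptake_bound >= 0)
  }
  structure(list(metabolite_id = metabolite_id, category = category,
                 uptake_bound = as.numeric(uptake_bound)),
            class = "MediumComponent")
}

#' Medium specification
#'
#' A named medium: a list of [medium_component()]s plus a total sugar
#' uptake budget (a.u.) split equally across the sugar components.
#'
#' @param name Medium name.
#' @param components List of [medium_component()]s.
#' @param sugar_budget Total sugar uptake (a.u.); default 10, the top of
#'   the 0-10 a.u. uptake range scanned in the simulations.
#' @return An object of class `MediumSpec`.
#' @export
medium_spec <- function(name, components, sugar_budget = 10) {
  stopifnot(is.numeric(sugar_budget), sugar_budget >= 0)
  structure(list(name = name, components = components,
                 sugar_budget = as.numeric(sugar_budget)),
            class = "MediumSpec")
}

medium_sugars <- function(medium) {
  vapply(Filter(function(co) co$category == "sugar", medium$components),
         `[[`, "", "metabolite_id")
}

#' Apply a medium to a model
#'
#' Translates a medium recipe into exchange-reaction bounds: all exchange
#' uptake is first closed (`lb = 0`) and all exchange secretion opened
#' (`ub = 1000`), then each component's exchange lower bound is set per its
#' category (see [medium_component()]). Sugars share `sugar_budget`
#' equally.
#'
#' @param model A `MetabolicModel`.
#' @param medium A `MediumSpec`.
#' @return A modified model copy.
#' @section Errors: a component whose metabolite has no exchange reaction
#'   raises an error naming the metabolite — on the real model this is
#'   exactly how the missing glucosamine transporter route manifests.
#' @export
apply_medium <- function(model, medium) {
  validate_model(model)
  stopifnot(inherits(medium, "MediumSpec"))
  for (rid in reaction_ids(model)) {
    if (model$reactions[[rid]]$is_exchange) {
      model <- set_bounds(model, rid, lower_bound = 0, upper_bound = 1000)
    }
  }
  sugars <- medium_sugars(medium)
  share <- if (length(sugars)) medium$sugar_budget / length(sugars) else 0
  for (co in medium$components) {
    ex <- exchange_for(model, co$metabolite_id)
    if (is.na(ex)) {
      stop("no exchange reaction for medium component: ", co$metabolite_id)
    }
    lb <- switch(co$category,
                 non_limiting = -1000,
                 limited_uptake = -co$uptake_bound,
                 sugar = -share,
                 secretion_only = 0)
    model <- set_bounds(model, ex, lower_bound = lb, upper_bound = 1000)
  }
  model
}

#' Predict growth on a medium
#'
#' Applies the medium and runs FBA on the biomass objective. A medium
#' supports growth when the optimum exceeds `threshold` (default `1e-6`
#' a.u. — far below the 0.09-0.13 a.u. scale of growing predictions, so
#' the yes/no call is insensitive to the exact value).
#'
#' @param model A `MetabolicModel`.
#' @param medium A `MediumSpec`.
#' @param objective_id Objective reaction (defaults to the model's).
#' @param threshold Growth threshold (a.u.).
#' @return A `GrowthPrediction`: list with `medium`, `grows` (logical),
#'   `mu_au` (FBA optimum, a.u.) and `note` (`""`, or `"no route"` when a
#'   medium component has no exchange reaction, in which case `grows =
#'   FALSE` and `mu_au = 0`).
#' @export
predict_growth <- function(model, medium, objective_id = model$objective_id,
                           threshold = 1e-6) {
  res <- tryCatch(
    fba_optimize(apply_medium(model, medium), objective_id),
    error = function(e) {
      if (grepl("no exchange reaction", conditionMessage(e))) {
        structure(list(status = "no_route",
                       message = conditionMessage(e)), class = "no_route")
      } else {
        stop(e)
      }
    })
  if (inherits(res, "no_route")) {
    return(structure(list(medium = medium$name, grows = FALSE, mu_au = 0,
                          note = res$message), class = "GrowthPrediction"))
  }
  mu <- if (res$status == "optimal") res$objective_value else 0
  structure(list(medium = medium$name, grows = mu > threshold, mu_au = mu,
                 note = ""), class = "GrowthPrediction")
}

#' Growth table across model versions and media
#'
#' One row per medium, one column pair (`grows`, `mu_au`) per model
#' version — the in-silico half of a growth-comparison table. Media whose
#' components lack an exchange route are recorded as no-growth with a
#' warning note rather than an error (the biological reading of the
#' missing glucosamine transporter).
#'
#' @param model_versions Named list of `MetabolicModel`s (names default to
#'   each model's `version_tag`).
#' @param media List of `MediumSpec`s.
#' @param threshold Growth threshold (a.u.).
#' @return Data frame with columns `medium`, then `<version>_grows`
#'   (`"y"`/`"n"`) and `<version>_au` per version, plus `note`.
#' @export
growth_table <- function(model_versions, media, threshold = 1e-6) {
  if (is.null(names(model_versions)) || any(!nzchar(names(model_versions)))) {
    names(model_versions) <- vapply(model_versions, `[[`, "", "version_tag")
  }
  out <- data.frame(medium = vapply(media, `[[`, "", "name"))
  notes <- rep("", length(media))
  for (vn in names(model_versions)) {
    preds <- lapply(media, function(md)
      predict_growth(model_versions[[vn]], md, threshold = threshold))
    out[[paste0(vn, "_grows")]] <- vapply(preds, function(p)
      if (p$grows) "y" else "n", "")
    out[[paste0(vn, "_au")]] <- vapply(preds, `[[`, 0, "mu_au")
    notes <- ifelse(nzchar(notes), notes,
                    vapply(preds, `[[`, "", "note"))
  }
  out$note <- notes
  out
}

#' Nutrient essentiality scan
#'
#' Removes one medium component at a time and re-predicts growth. A
#' component is essential when its omission drops the optimum below the
#' growth threshold (the in-silico version of the L-threonine omission
#' experiment).
#'
#' @param model A `MetabolicModel`.
#' @param medium A `MediumSpec` that supports growth (else an error).
#' @param objective_id Objective reaction.
#' @param threshold Growth threshold (a.u.).
#' @return Data frame with columns `metabolite_id`, `category`,
#'   `essential` (logical), `mu_without` (a.u.).
#' @export
essentiality_scan <- function(model, medium, objective_id = model$objective_id,
                              threshold = 1e-6) {
  base <- predict_growth(model, medium, objective_id, threshold)
  if (!base$grows) {
    stop("essentiality scan undefined: base medium does not support growth")
  }
  rows <- lapply(seq_along(medium$components), function(i) {
    reduced <- medium
    reduced$components <- medium$components[-i]
    p <- predict_growth(model, reduced, objective_id, threshold)
    data.frame(metabolite_id = medium$components[[i]]$metabolite_id,
               category = medium$components[[i]]$category,
               essential = !p$grows, mu_without = p$mu_au)
  })
  do.call(rbind, rows)
}

#' Sugar uptake-bound scan
#'
#' Re-predicts growth for a grid of uptake bounds of one sugar, the other
#' medium components unchanged — the 0-10 a.u. uptake-rate scan of the
#' simulations. The optimum is non-decreasing in the bound (an LP
#' relaxation property).
#'
#' @param model A `MetabolicModel`.
#' @param medium A `MediumSpec` containing `sugar_id` among its sugars.
#' @param sugar_id Sugar metabolite id to scan.
#' @param grid Numeric vector of non-negative uptake bounds (a.u.).
#' @param objective_id Objective reaction.
#' @return Data frame with columns `bound` and `mu_au`.
#' @export
uptake_scan <- function(model, medium, sugar_id, grid = seq(0, 10, by = 1),
                        objective_id = model$objective_id) {
  stopifnot(all(grid >= 0))
  if (!sugar_id %in% medium_sugars(medium)) {
    stop("unknown sugar in medium: ", sugar_id)
  }
  applied <- apply_medium(model, medium)
  ex <- exchange_for(applied, sugar_id)
  mu <- vapply(grid, function(b) {
    m <- set_bounds(applied, ex, lower_bound = -b)
    res <- fba_optimize(m, objective_id)
    if (res$status == "optimal") res$objective_value else 0
  }, 0)
  data.frame(bound = grid, mu_au = mu)
}

#' Compare flux distributions across media
#'
#' For each medium, computes the FVA range of every reaction at the fixed
#' optimum (fraction 1.0) and its midpoint, then classifies each reaction's
#' flux magnitude in each medium against the first (reference) medium:
#' `"similar"` when the relative difference of `|midpoint|`s is within
#' `rel_tol` (or both are below `abs_tol`), else `"higher"` / `"lower"`.
#' This is the tabular counterpart of arrow-width flux maps comparing
#' substrates at equimolar total sugar.
#'
#' @param model A `MetabolicModel`.
#' @param media List of `MediumSpec`s, each supporting growth.
#' @param rel_tol Relative-difference threshold (default 0.1).
#' @param abs_tol Absolute flux floor (a.u.) below which fluxes are treated
#'   as zero (default `1e-6`).
#' @return Data frame with one row per reaction: `reaction_id`, then per
#'   medium `<name>_min`, `<name>_max`, `<name>_mid`, and per non-reference
#'   medium `<name>_class`.
#' @export
compare_flux_distributions <- function(model, media, rel_tol = 0.1,
                                       abs_tol = 1e-6) {
  stopifnot(length(media) >= 1)
  fvas <- lapply(media, function(md) {
    applied <- apply_medium(model, md)
    base <- fba_optimize(applied)
    if (base$status != "optimal" || base$objective_value <= 1e-6) {
      stop("medium does not support growth: ", md$name)
    }
    flux_variability(applied)
  })
  out <- data.frame(reaction_id = fvas[[1]]$reaction_id)
  mids <- list()
  for (k in seq_along(media)) {
    nm <- media[[k]]$name
    out[[paste0(nm, "_min")]] <- fvas[[k]]$min_flux
    out[[paste0(nm, "_max")]] <- fvas[[k]]$max_flux
    mids[[k]] <- (fvas[[k]]$min_flux + fvas[[k]]$max_flux) / 2
    out[[paste0(nm, "_mid")]] <- mids[[k]]
  }
  ref <- abs(mids[[1]])
  for (k in seq_along(media)[-1]) {
    cur <- abs(mids[[k]])
    cls <- mapply(function(a, b) {
      if (a < abs_tol && b < abs_tol) return("similar")
      if (abs(a - b) <= rel_tol * max(a, b)) return("similar")
      if (a > b) "higher" else "lower"
    }, cur, ref)
    out[[paste0(media[[k]]$name, "_class")]] <- cls
  }
  out
}

#' Read a medium from JSON
#'
#' On-disk form: `{"name": ..., "sugar_budget": ..., "components":
#' [{"metabolite": ..., "category": ..., "bound": ...}, ...]}`.
#'
#' @param path JSON file path.
#' @return A `MediumSpec`.
#' @export
read_medium <- function(path) {
  x <- jsonlite::read_json(path)
  comps <- lapply(x$components, function(co) {
    medium_component(co$metabolite, co$category,
                     uptake_bound = if (is.null(co$bound)) NA_real_
                                    else as.numeric(co$bound))
  })
  medium_spec(x$name, comps,
              sugar_budget = if (is.null(x$sugar_budget)) 10
                             else as.numeric(x$sugar_budget))
}

#' Write a medium to JSON
#'
#' @param medium A `MediumSpec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(medium, path) {
  x <- list(name = medium$name, sugar_budget = medium$sugar_budget,
            components = lapply(medium$components, function(co) {
              out <- list(metabolite = co$metabolite_id,
                          category = co$category)
              if (!is.na(co$uptake_bound)) out$bound <- co$uptake_bound
              out
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled media for the six growth-comparison conditions
#'
#' The six sugar conditions of the growth-comparison experiment (glucose +
#' GlcN, GlcN, GlcNAc, GlcNAc + glucose, GalNAc, glucose) on the CP mineral
#' base mapped to the toy amino-sugar core's exchange ids: threonine at a
#' limited uptake of 1 a.u., ammonium and trace components (water,
#' phosphate) non-limiting, acetate and propionate secretion-only, sugars
#' sharing a budget of 10 a.u. Shipped as JSON under
#' `inst/extdata/media/` so the recipes are data, not code.
#'
#' @param dir Directory of medium JSON files; defaults to the bundled set.
#' @return Named list of `MediumSpec`s, in the fixed condition order
#'   `glucose_glcn`, `glcn`, `glcnac`, `glcnac_glucose`, `galnac`,
#'   `glucose`.
#' @export
bundled_media <- function(dir = system.file("extdata", "media",
                                            package = "mucimin")) {
  order <- c("glucose_glcn", "glcn", "glcnac", "glcnac_glucose",
             "galnac", "glucose")
  files <- file.path(dir, paste0(order, ".json"))
  missing <- !file.exists(files)
  if (any(missing)) stop("missing medium file(s): ",
                         paste(files[missing], collapse = ", "))
  stats::setNames(lapply(files, read_medium), order)
}
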