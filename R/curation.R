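#' Curation step
#'
#' One edit to a metabolic model. Three kinds are supported:
#' \describe{
#'   \item{`remove_reaction`}{`payload` is a reaction id. Used for the v1 to
#'     v2 adjustment that deletes the gap-filled glucosamine-6-phosphate
#'     amination (GlmS, EC 2.6.1.16), absent from A. muciniphila.}
#'   \item{`add_reaction`}{`payload` is a list with `id`, `equation` (or
#'     `stoichiometry`), `lower_bound`, `upper_bound`, optional `name`,
#'     `annotation`, and optional `new_metabolites` (list of lists with
#'     `id`, `compartment`, optional `name`). Used to add the UDP-GlcNAc
#'     4-epimerase supporting growth on GalNAc.}
#'   \item{`set_bounds`}{`payload` is a list with `id` and new
#'     `lower_bound` / `upper_bound`.}
#' }
#'
#' @param kind One of `"remove_reaction"`, `"add_reaction"`, `"set_bounds"`.
#' @param payload See Details.
#' @param rationale Free-text justification recorded in the log.
#' @return An object of class `CurationStep`.
#' @export
curation_step <- function(kind = c("remove_reaction", "add_reaction", "set_bounds"),
                          payload, rationale = "") {
  kind <- match.arg(kind)
  if (kind == "remove_reaction") {
    stopifnot(is.character(payload), length(payload) == 1L)
  } else {
    stopifnot(is.list(payload), !is.null(payload$id))
  }
  structure(list(kind = kind, payload = payload, rationale = rationale),
            class = "CurationStep")
}

payload_to_reaction <- function(payload) {
  st <- if (!is.null(payload$stoichiometry)) {
    unlist(payload$stoichiometry)
  } else if (!is.null(payload$equation)) {
    parse_equation(payload$equation)$stoichiometry
  } else {
    stop("add_reaction payload needs 'stoichiometry' or 'equation'")
  }
  reaction(payload$id, st,
           name = if (is.null(payload$name)) payload$id else payload$name,
           lower_bound = if (is.null(payload$lower_bound)) 0 else payload$lower_bound,
           upper_bound = if (is.null(payload$upper_bound)) 1000 else payload$upper_bound,
           annotation = if (is.null(payload$annotation)) character()
                        else unlist(payload$annotation))
}

#' Apply curation steps to a model
#'
#' Applies the steps in order to a copy of `model` and records a replayable
#' log with before/after state. The input model is never modified.
#'
#' @param model A `MetabolicModel`.
#' @param steps List of [curation_step()] objects (possibly empty).
#' @return List with elements `model` (the curated model, `version_tag`
#'   unchanged — callers relabel) and `log` (a `CurationLog`: list of
#'   applied steps with `before` / `after` snapshots).
#' @export
apply_curation <- function(model, steps) {
  validate_model(model)
  out <- model
  log <- list()
  for (s in steps) {
    stopifnot(inherits(s, "CurationStep"))
    if (s$kind == "remove_reaction") {
      rid <- s$payload
      if (!rid %in% reaction_ids(out)) {
        stop("cannot remove absent reaction: ", rid)
      }
      before <- out$reactions[[rid]]
      out$reactions[[rid]] <- NULL
      log[[length(log) + 1L]] <- list(step = s, before = before, after = NULL)
    } else if (s$kind == "add_reaction") {
      r <- payload_to_reaction(s$payload)
      if (r$id %in% reaction_ids(out)) {
        stop("cannot add duplicate reaction id: ", r$id)
      }
      if (!is.null(s$payload$new_metabolites)) {
        for (nm in s$payload$new_metabolites) {
          if (!nm$id %in% metabolite_ids(out)) {
            out$metabolites[[nm$id]] <- metabolite(
              nm$id, name = if (is.null(nm$name)) nm$id else nm$name,
              compartment = if (is.null(nm$compartment)) "cytosol"
                            else nm$compartment)
          }
        }
      }
      missing <- setdiff(names(r$stoichiometry), metabolite_ids(out))
      if (length(missing)) {
        stop("added reaction ", r$id, " references undeclared metabolite: ",
             paste(missing, collapse = ", "),
             " (declare via payload$new_metabolites)")
      }
      out$reactions[[r$id]] <- r
      log[[length(log) + 1L]] <- list(step = s, before = NULL, after = r)
    } else { # set_bounds
      rid <- s$payload$id
      if (!rid %in% reaction_ids(out)) {
        stop("cannot set bounds of absent reaction: ", rid)
      }
      before <- out$reactions[[rid]]
      out <- set_bounds(out, rid,
                        lower_bound = if (is.null(s$payload$lower_bound)) NA
                                      else s$payload$lower_bound,
                        upper_bound = if (is.null(s$payload$upper_bound)) NA
                                      else s$payload$upper_bound)
      log[[length(log) + 1L]] <- list(step = s, before = before,
                                      after = out$reactions[[rid]])
    }
  }
  validate_model(out)
  list(model = out, log = structure(log, class = "CurationLog"))
}

#' Diff two models as a curation log
#'
#' Computes curation steps that transform `a` into `b` (up to list order):
#' removals, additions, and bound changes for reactions whose stoichiometry
#' is unchanged. A reaction present in both with different stoichiometry
#' becomes a remove + add pair.
#'
#' @param a,b Valid `MetabolicModel` objects.
#' @param tol Numeric tolerance below which coefficients and bounds count
#'   as unchanged (default `1e-9`).
#' @return List of [curation_step()] objects; empty when the models are
#'   structurally equal. `apply_curation(a, diff_models(a, b))$model` is
#'   structurally equal to `b`.
#' @export
diff_models <- function(a, b, tol = 1e-9) {
  validate_model(a); validate_model(b)
  steps <- list()
  add_step <- function(s) steps[[length(steps) + 1L]] <<- s
  new_mets <- setdiff(metabolite_ids(b), metabolite_ids(a))
  for (rid in setdiff(reaction_ids(a), reaction_ids(b))) {
    add_step(curation_step("remove_reaction", rid, "present in source only"))
  }
  mk_add <- function(r) {
    nm <- intersect(names(r$stoichiometry), new_mets)
    curation_step("add_reaction", list(
      id = r$id, name = r$name,
      equation = format_equation(r$stoichiometry,
                                 reversible = r$lower_bound < 0 && r$upper_bound > 0),
      lower_bound = r$lower_bound, upper_bound = r$upper_bound,
      annotation = r$annotation,
      new_metabolites = lapply(nm, function(id) {
        m <- b$metabolites[[id]]
        list(id = m$id, name = m$name, compartment = m$compartment)
      })), "present in target only")
  }
  for (rid in intersect(reaction_ids(a), reaction_ids(b))) {
    ra <- a$reactions[[rid]]; rb <- b$reactions[[rid]]
    same_st <- setequal(names(ra$stoichiometry), names(rb$stoichiometry)) &&
      all(abs(ra$stoichiometry[names(rb$stoichiometry)] -
              rb$stoichiometry) <= tol)
    if (!same_st) {
      add_step(curation_step("remove_reaction", rid, "stoichiometry changed"))
      add_step(mk_add(rb))
    } else if (abs(ra$lower_bound - rb$lower_bound) > tol ||
               abs(ra$upper_bound - rb$upper_bound) > tol) {
      add_step(curation_step("set_bounds",
        list(id = rid, lower_bound = rb$lower_bound,
             upper_bound = rb$upper_bound), "bounds changed"))
    }
  }
  for (rid in setdiff(reaction_ids(b), reaction_ids(a))) {
    add_step(mk_add(b$reactions[[rid]]))
  }
  steps
}

#' Read curation steps from JSON
#'
#' The on-disk form is a JSON array of objects with fields `kind`,
#' `payload`, `rationale`, so a model-version recipe ships as data.
#'
#' @param path JSON file path.
#' @return List of [curation_step()] objects.
#' @export
read_curation <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) {
    payload <- if (identical(x$kind, "remove_reaction")) x$payload[[1]] %||%
      x$payload else x$payload
    if (identical(x$kind, "remove_reaction") && is.list(payload)) {
      payload <- unlist(payload)
    }
    curation_step(x$kind, payload,
                  rationale = if (is.null(x$rationale)) "" else x$rationale)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write curation steps to JSON
#'
#' @param steps List of [curation_step()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curation <- function(steps, path) {
  jsonlite::write_json(lapply(steps, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
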