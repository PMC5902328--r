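#' Metabolite
#'
#' A single chemical species of a metabolic model. Compartments follow the
#' two-compartment convention of the Akkermansia muciniphila reconstruction:
#' everything is either cytosolic or extracellular.
#'
#' @param id Unique identifier (letters, digits, `_`, `.`, `-`; must not
#'   start with a digit).
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Either `"cytosol"` or `"extracellular"`.
#' @param formula Optional elemental formula string (`NA` if unknown).
#' @return An object of class `Metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = c("cytosol", "extracellular"),
                       formula = NA_character_) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("^[0-9]", id) || grepl("[^A-Za-z0-9_.-]", id)) {
    stop("invalid metabolite id: ", id)
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula),
            class = "Metabolite")
}

#' Reaction
#'
#' A stoichiometric conversion with flux bounds. Negative coefficients mark
#' consumed metabolites, positive coefficients produced ones. Reversibility
#' is encoded purely through the bounds (reversible iff `lower_bound < 0 <
#' upper_bound`); there is no separate flag. A reaction touching exactly one
#' metabolite is an exchange reaction: negative flux means uptake from the
#' environment, positive flux secretion.
#'
#' @param id Unique identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient. Must be non-empty with no zero entries.
#' @param name Human-readable name.
#' @param lower_bound,upper_bound Flux bounds (a.u.); must be finite with
#'   `lower_bound <= upper_bound`.
#' @param annotation Optional character vector of EC numbers / locus tags.
#' @return An object of class `Reaction` with an `is_exchange` field set
#'   automatically.
#' @export
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = 0, upper_bound = 1000,
                     annotation = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("^[0-9]", id) || grepl("[^A-Za-z0-9_.-]", id)) {
    stop("invalid reaction id: ", id)
  }
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("reaction ", id, ": stoichiometry must be a non-empty named vector")
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop("reaction ", id, ": stoichiometry has only zero coefficients")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("reaction ", id, ": duplicated metabolite in stoichiometry")
  }
  if (!is.finite(lower_bound) || !is.finite(upper_bound)) {
    stop("reaction ", id, ": bounds must be finite")
  }
  if (lower_bound > upper_bound) {
    stop("reaction ", id, ": lower_bound > upper_bound")
  }
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 is_exchange = length(stoichiometry) == 1L,
                 annotation = annotation),
            class = "Reaction")
}

#' Metabolic model
#'
#' Container for a constraint-based metabolic model: metabolites, reactions
#' and a biomass objective. The stoichiometric matrix S (metabolites x
#' reactions) is derived on demand with [stoichiometric_matrix()].
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param objective_id Id of the objective (biomass) reaction.
#' @param version_tag Free-text model version label (e.g. `"v1"`, `"v2"`).
#' @param id Model identifier.
#' @return An object of class `MetabolicModel`.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id,
                            version_tag = "v1", id = "model") {
  mets <- stats::setNames(metabolites, vapply(metabolites, `[[`, "", "id"))
  rxns <- stats::setNames(reactions, vapply(reactions, `[[`, "", "id"))
  m <- structure(list(id = id, version_tag = version_tag,
                      metabolites = mets, reactions = rxns,
                      objective_id = objective_id),
                 class = "MetabolicModel")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, every metabolite referenced
#' by a reaction is declared, bounds ordered, the objective reaction exists,
#' and the exchange flag agrees with the single-metabolite rule.
#'
#' @param model A `MetabolicModel`.
#' @return `TRUE` invisibly; otherwise an error describing the first
#'   violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "MetabolicModel"))
  met_ids <- vapply(model$metabolites, `[[`, "", "id")
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id: ", met_ids[duplicated(met_ids)][1])
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id: ", rxn_ids[duplicated(rxn_ids)][1])
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction ", r$id, " references undeclared metabolite: ",
           paste(missing, collapse = ", "))
    }
    if (r$lower_bound > r$upper_bound) {
      stop("reaction ", r$id, ": lower_bound > upper_bound")
    }
    if (r$is_exchange != (length(r$stoichiometry) == 1L)) {
      stop("reaction ", r$id, ": inconsistent exchange flag")
    }
  }
  if (length(model$reactions) &&
      !model$objective_id %in% rxn_ids) {
    stop("objective reaction not in model: ", model$objective_id)
  }
  invisible(TRUE)
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf("MetabolicModel '%s' (%s): %d reactions, %d metabolites, objective '%s'\n",
              x$id, x$version_tag, length(x$reactions),
              length(x$metabolites), x$objective_id))
  invisible(x)
}

#' @export
print.Reaction <- function(x, ...) {
  cat(sprintf("%s: %s  [%g, %g]%s\n", x$id, format_equation(x$stoichiometry,
              reversible = x$lower_bound < 0 && x$upper_bound > 0),
              x$lower_bound, x$upper_bound,
              if (x$is_exchange) "  (exchange)" else ""))
  invisible(x)
}

reaction_ids <- function(model) names(model$reactions)
metabolite_ids <- function(model) names(model$metabolites)

#' Stoichiometric matrix
#'
#' Builds the sparse stoichiometric matrix S (metabolites x reactions).
#' Entry (i, j) is the signed coefficient of metabolite i in reaction j.
#'
#' @param model A `MetabolicModel`.
#' @return A `Matrix::sparseMatrix` with metabolite ids as row names and
#'   reaction ids as column names; `0 x 0` for an empty model.
#' @export
stoichiometric_matrix <- function(model) {
  validate_model(model)
  met_ids <- metabolite_ids(model)
  rxn_ids <- reaction_ids(model)
  if (length(met_ids) == 0L || length(rxn_ids) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(met_ids), length(rxn_ids)),
                                dimnames = list(met_ids, rxn_ids)))
  }
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Bounds of all reactions
#'
#' @param model A `MetabolicModel`.
#' @return Data frame with columns `id`, `lower_bound`, `upper_bound`.
#' @export
reaction_bounds <- function(model) {
  data.frame(id = reaction_ids(model),
             lower_bound = vapply(model$reactions, `[[`, 0, "lower_bound"),
             upper_bound = vapply(model$reactions, `[[`, 0, "upper_bound"),
             row.names = NULL)
}

#' Set the bounds of one reaction
#'
#' @param model A `MetabolicModel`.
#' @param reaction_id Reaction to modify.
#' @param lower_bound,upper_bound New bounds; `NA` keeps the current value.
#' @return A modified copy of the model (the input is never changed).
#' @export
set_bounds <- function(model, reaction_id, lower_bound = NA, upper_bound = NA) {
  if (!reaction_id %in% reaction_ids(model)) {
    stop("unknown reaction: ", reaction_id)
  }
  r <- model$reactions[[reaction_id]]
  if (!is.na(lower_bound)) r$lower_bound <- as.numeric(lower_bound)
  if (!is.na(upper_bound)) r$upper_bound <- as.numeric(upper_bound)
  if (r$lower_bound > r$upper_bound) {
    stop("reaction ", reaction_id, ": lower_bound > upper_bound")
  }
  model$reactions[[reaction_id]] <- r
  model
}

#' Find the exchange reaction of a metabolite
#'
#' @param model A `MetabolicModel`.
#' @param metabolite_id Metabolite whose boundary exchange is wanted.
#' @return The reaction id, or `NA_character_` when the metabolite has no
#'   exchange reaction (e.g. glucosamine in the A. muciniphila model, which
#'   lacks a GlcN transporter route).
#' @export
exchange_for <- function(model, metabolite_id) {
  for (r in model$reactions) {
    if (r$is_exchange && names(r$stoichiometry) == metabolite_id) {
      return(r$id)
    }
  }
  NA_character_
}

#' Structural equality of two models
#'
#' Compares metabolite and reaction sets, stoichiometries, bounds and the
#' objective, ignoring list order. Numeric differences below `tol` are
#' treated as equal.
#'
#' @param a,b `MetabolicModel` objects.
#' @param tol Numeric tolerance (default `1e-9`).
#' @return Logical scalar.
#' @export
structurally_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(metabolite_ids(a), metabolite_ids(b))) return(FALSE)
  if (!setequal(reaction_ids(a), reaction_ids(b))) return(FALSE)
  if (!identical(a$objective_id, b$objective_id)) return(FALSE)
  for (id in metabolite_ids(a)) {
    if (!identical(a$metabolites[[id]]$compartment,
                   b$metabolites[[id]]$compartment)) return(FALSE)
  }
  for (id in reaction_ids(a)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    if (!setequal(names(ra$stoichiometry), names(rb$stoichiometry))) return(FALSE)
    if (any(abs(ra$stoichiometry[names(rb$stoichiometry)] -
                rb$stoichiometry) > tol)) return(FALSE)
    if (abs(ra$lower_bound - rb$lower_bound) > tol) return(FALSE)
    if (abs(ra$upper_bound - rb$upper_bound) > tol) return(FALSE)
  }
  TRUE
}

#' Drop metabolites referenced by no reaction
#'
#' Curation that removes reactions can leave orphan metabolites behind
#' (e.g. the glutamine/glutamate pair after deleting the GlmS amination);
#' this removes them so the curated model matches a freshly built one.
#'
#' @param model A `MetabolicModel`.
#' @return A modified copy without unreferenced metabolites.
#' @export
prune_unused_metabolites <- function(model) {
  used <- unique(unlist(lapply(model$reactions, function(r)
    names(r$stoichiometry))))
  model$metabolites <- model$metabolites[
    vapply(model$metabolites, `[[`, "", "id") %in% used]
  model
}

# --- reaction equation grammar -------------------------------------------
# "2 A + B --> C"  irreversible;  "A <=> B" reversible;  "A -->" sink/exchange.

parse_equation <- function(eq) {
  eq <- trimws(eq)
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("-->", eq, fixed = TRUE)) "-->" else
      stop("equation has no arrow ('-->' or '<=>'): ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    st <- numeric(length(terms)); ids <- character(length(terms))
    for (k in seq_along(terms)) {
      parts <- strsplit(terms[k], "[[:space:]]+")[[1]]
      if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient in term: ", terms[k])
        st[k] <- sign * coef; ids[k] <- parts[2]
      } else if (length(parts) == 1L) {
        st[k] <- sign; ids[k] <- parts[1]
      } else {
        stop("bad equation term: ", terms[k])
      }
    }
    stats::setNames(st, ids)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  # merge duplicates (metabolite on both sides)
  tapply_sum <- tapply(st, names(st), sum)
  st <- stats::setNames(as.numeric(tapply_sum), names(tapply_sum))
  st <- st[order(names(st))]
  list(stoichiometry = st[st != 0], reversible = arrow == "<=>")
}

format_equation <- function(stoichiometry, reversible = FALSE) {
  fmt_side <- function(st) {
    if (length(st) == 0L) return("")
    st <- st[order(names(st))]
    paste(vapply(seq_along(st), function(k) {
      coef <- abs(st[k])
      if (abs(coef - 1) < 1e-12) names(st)[k]
      else paste(format(coef, digits = 12, scientific = FALSE), names(st)[k])
    }, ""), collapse = " + ")
  }
  lhs <- fmt_side(stoichiometry[stoichiometry < 0])
  rhs <- fmt_side(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "-->"
  trimws(paste(lhs, arrow, rhs))
}
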