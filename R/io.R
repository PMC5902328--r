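#' Read a metabolic model
#'
#' Reads a constraint-based model from SBML (Level 2 COBRA dialect, or a
#' basic Level 3 + fbc subset) or from tab-separated tables.
#'
#' For SBML, flux bounds are taken from fbc constructs when present,
#' otherwise from `LOWER_BOUND` / `UPPER_BOUND` kinetic-law parameters,
#' otherwise defaulted from the `reversible` attribute (`-1000/1000` vs
#' `0/1000`). The objective is taken from an explicit fbc objective or an
#' `OBJECTIVE_COEFFICIENT` kinetic-law parameter when present, else the
#' first reaction whose id matches `biomass` (case-insensitive). Species
#' with `boundaryCondition="true"` are dropped from stoichiometries, and
#' `M_` / `R_` id prefixes are stripped.
#'
#' The table format is a pair of TSV files `<stem>_reactions.tsv`
#' (columns `id`, `name`, `equation`, `lower_bound`, `upper_bound`,
#' `objective`) and `<stem>_metabolites.tsv` (columns `id`, `name`,
#' `compartment`, `formula`); `path` is the stem. Equations use the grammar
#' `"2 A + B --> C"` with `<=>` for reversible reactions and an empty side
#' for boundary reactions.
#'
#' @param path File path (SBML) or file stem (table format).
#' @param format `"sbml"` or `"table"`.
#' @return A validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("sbml", "table")) {
  format <- match.arg(format)
  if (format == "sbml") read_model_sbml(path) else read_model_table(path)
}

#' Write a metabolic model
#'
#' Inverse of [read_model()]: SBML Level 2 (COBRA dialect, bounds and
#' objective as kinetic-law parameters) or the TSV table pair. Reading a
#' written model returns a structurally identical model.
#'
#' @param model A valid `MetabolicModel`.
#' @param path Output file path (SBML) or stem (table).
#' @param format `"sbml"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("sbml", "table")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "sbml") write_model_sbml(model, path) else
    write_model_table(model, path)
  invisible(path)
}

compartment_code <- c(cytosol = "c", extracellular = "e")

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4",
    level = "2", version = "4")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             name = paste(model$id, model$version_tag))
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (code in unique(compartment_code[vapply(model$metabolites, `[[`, "",
                                              "compartment")])) {
    xml2::xml_add_child(comps, "compartment", id = code, size = "1")
  }
  if (length(model$metabolites)) {
    sp <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (m in model$metabolites) {
      node <- xml2::xml_add_child(sp, "species",
        id = paste0("M_", m$id), name = m$name,
        compartment = compartment_code[[m$compartment]],
        boundaryCondition = "false")
      if (!is.na(m$formula)) xml2::xml_set_attr(node, "formula", m$formula)
    }
  }
  rx <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rev <- r$lower_bound < 0 && r$upper_bound > 0
    node <- xml2::xml_add_child(rx, "reaction", id = paste0("R_", r$id),
                                name = r$name,
                                reversible = if (rev) "true" else "false")
    if (length(r$annotation)) {
      notes <- xml2::xml_add_child(node, "notes")
      body <- xml2::xml_add_child(notes, "body",
        xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p",
        paste0("ANNOTATION: ", paste(r$annotation, collapse = "; ")))
    }
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (k in seq_along(reac)) {
        xml2::xml_add_child(lr, "speciesReference",
          species = paste0("M_", names(reac)[k]),
          stoichiometry = format(abs(reac[k]), digits = 15, scientific = FALSE))
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lp, "speciesReference",
          species = paste0("M_", names(prod)[k]),
          stoichiometry = format(abs(prod[k]), digits = 15, scientific = FALSE))
      }
    }
    kl <- xml2::xml_add_child(node, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    xml2::xml_add_child(math, "ci", "FLUX_VALUE")
    params <- xml2::xml_add_child(kl, "listOfParameters")
    fmt <- function(x) format(x, digits = 15, scientific = FALSE)
    xml2::xml_add_child(params, "parameter", id = "LOWER_BOUND",
                        value = fmt(r$lower_bound))
    xml2::xml_add_child(params, "parameter", id = "UPPER_BOUND",
                        value = fmt(r$upper_bound))
    xml2::xml_add_child(params, "parameter", id = "OBJECTIVE_COEFFICIENT",
                        value = if (r$id == model$objective_id) "1" else "0")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

strip_prefix <- function(id, prefix) {
  sub(paste0("^", prefix), "", id)
}

read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  level <- xml2::xml_attr(doc, "level")
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML format error: no <model> element")

  code_to_comp <- c(c = "cytosol", e = "extracellular")
  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  boundary <- character()
  mets <- list()
  for (s in sp_nodes) {
    sid <- xml2::xml_attr(s, "id")
    if (identical(xml2::xml_attr(s, "boundaryCondition"), "true")) {
      boundary <- c(boundary, sid)
      next
    }
    comp <- xml2::xml_attr(s, "compartment")
    comp <- if (comp %in% names(code_to_comp)) code_to_comp[[comp]] else
      if (comp %in% code_to_comp) comp else "cytosol"
    formula <- xml2::xml_attr(s, "formula")
    mets[[length(mets) + 1L]] <- metabolite(
      strip_prefix(sid, "M_"),
      name = if (is.na(xml2::xml_attr(s, "name"))) strip_prefix(sid, "M_")
             else xml2::xml_attr(s, "name"),
      compartment = comp,
      formula = if (is.na(formula)) NA_character_ else formula)
  }
  met_ids <- vapply(mets, `[[`, "", "id")

  num_attr <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  # L3 fbc global parameters (flux bounds referenced by id)
  gpar <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  par_vals <- stats::setNames(vapply(gpar, num_attr, 0, name = "value"),
                              xml2::xml_attr(gpar, "id"))

  rxn_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  rxns <- list()
  objective_id <- NA_character_
  for (rn in rxn_nodes) {
    rid_raw <- xml2::xml_attr(rn, "id")
    if (is.na(rid_raw)) stop("SBML format error: reaction without id")
    rid <- strip_prefix(rid_raw, "R_")
    side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rn, xpath)
      if (length(refs) == 0L) return(numeric())
      ids <- xml2::xml_attr(refs, "species")
      coefs <- vapply(refs, function(x) {
        v <- num_attr(x, "stoichiometry")
        if (is.na(v)) 1 else v
      }, 0)
      keep <- !(ids %in% boundary)
      stats::setNames(sign * coefs[keep], strip_prefix(ids[keep], "M_"))
    }
    st <- c(side("./listOfReactants/speciesReference", -1),
            side("./listOfProducts/speciesReference", +1))
    if (length(st) == 0L) next  # pure-boundary reaction, nothing to balance
    missing <- setdiff(names(st), met_ids)
    if (length(missing)) {
      stop("validation error: reaction ", rid,
           " references undeclared metabolite: ",
           paste(missing, collapse = ", "))
    }
    reversible <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    lb <- NA_real_; ub <- NA_real_; objc <- NA_real_
    # precedence 1: fbc flux-bound attributes (L3)
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_vals)) lb <- par_vals[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_vals)) ub <- par_vals[[ub_ref]]
    # precedence 2: kinetic-law parameters (L2 COBRA dialect)
    kpar <- xml2::xml_find_all(rn, "./kineticLaw/listOfParameters/parameter")
    if (length(kpar)) {
      kv <- stats::setNames(vapply(kpar, num_attr, 0, name = "value"),
                            xml2::xml_attr(kpar, "id"))
      if (is.na(lb) && "LOWER_BOUND" %in% names(kv)) lb <- kv[["LOWER_BOUND"]]
      if (is.na(ub) && "UPPER_BOUND" %in% names(kv)) ub <- kv[["UPPER_BOUND"]]
      if ("OBJECTIVE_COEFFICIENT" %in% names(kv)) objc <- kv[["OBJECTIVE_COEFFICIENT"]]
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000
    ann <- character()
    note <- xml2::xml_find_first(rn, ".//p[starts-with(text(), 'ANNOTATION: ')]")
    if (!inherits(note, "xml_missing")) {
      ann <- strsplit(sub("^ANNOTATION: ", "", xml2::xml_text(note)), "; ")[[1]]
    }
    rxns[[length(rxns) + 1L]] <- reaction(
      rid, st, name = if (is.na(xml2::xml_attr(rn, "name"))) rid
                      else xml2::xml_attr(rn, "name"),
      lower_bound = lb, upper_bound = ub, annotation = ann)
    if (!is.na(objc) && objc != 0) objective_id <- rid
  }
  # explicit L3 fbc objective wins over kinetic-law coefficients
  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    ref <- xml2::xml_attr(fo, "reaction")
    if (!is.na(ref)) objective_id <- strip_prefix(ref, "R_")
  }
  if (is.na(objective_id)) {
    rids <- vapply(rxns, `[[`, "", "id")
    hit <- grep("biomass", rids, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) stop("SBML format error: no objective reaction ",
                                "(explicit or named 'biomass') found")
    objective_id <- hit[1]
  }
  mid <- xml2::xml_attr(mdl, "id")
  metabolic_model(mets, rxns, objective_id,
                  version_tag = if (is.na(level)) "" else paste0("L", level),
                  id = if (is.na(mid)) "model" else mid)
}

write_model_table <- function(model, stem) {
  rdf <- data.frame(
    id = reaction_ids(model),
    name = vapply(model$reactions, `[[`, "", "name"),
    equation = vapply(model$reactions, function(r)
      format_equation(r$stoichiometry,
                      reversible = r$lower_bound < 0 && r$upper_bound > 0), ""),
    lower_bound = vapply(model$reactions, `[[`, 0, "lower_bound"),
    upper_bound = vapply(model$reactions, `[[`, 0, "upper_bound"),
    objective = as.integer(reaction_ids(model) == model$objective_id),
    row.names = NULL)
  mdf <- data.frame(
    id = metabolite_ids(model),
    name = vapply(model$metabolites, `[[`, "", "name"),
    compartment = vapply(model$metabolites, `[[`, "", "compartment"),
    formula = vapply(model$metabolites, function(m)
      if (is.na(m$formula)) "" else m$formula, ""),
    row.names = NULL)
  rpath <- paste0(stem, "_reactions.tsv")
  mpath <- paste0(stem, "_metabolites.tsv")
  con <- file(rpath, "w")
  writeLines(sprintf("# model\t%s\t%s", model$id, model$version_tag), con)
  utils::write.table(rdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  utils::write.table(mdf, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

read_model_table <- function(stem) {
  rpath <- paste0(stem, "_reactions.tsv")
  mpath <- paste0(stem, "_metabolites.tsv")
  for (p in c(rpath, mpath)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  header <- readLines(rpath, n = 1L)
  model_id <- "model"; version_tag <- ""
  if (startsWith(header, "# model\t")) {
    parts <- strsplit(header, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) model_id <- parts[2]
    if (length(parts) >= 3) version_tag <- parts[3]
  }
  rdf <- utils::read.delim(rpath, comment.char = "#", stringsAsFactors = FALSE)
  mdf <- utils::read.delim(mpath, stringsAsFactors = FALSE)
  for (col in c("id", "equation", "lower_bound", "upper_bound")) {
    if (!col %in% names(rdf)) stop("table format error: reactions sheet ",
                                   "lacks column '", col, "'")
  }
  for (col in c("id", "compartment")) {
    if (!col %in% names(mdf)) stop("table format error: metabolites sheet ",
                                   "lacks column '", col, "'")
  }
  mets <- lapply(seq_len(nrow(mdf)), function(i) {
    metabolite(mdf$id[i],
               name = if ("name" %in% names(mdf)) mdf$name[i] else mdf$id[i],
               compartment = mdf$compartment[i],
               formula = if ("formula" %in% names(mdf) && nzchar(mdf$formula[i]))
                 mdf$formula[i] else NA_character_)
  })
  rxns <- lapply(seq_len(nrow(rdf)), function(i) {
    eq <- parse_equation(rdf$equation[i])
    reaction(rdf$id[i], eq$stoichiometry,
             name = if ("name" %in% names(rdf)) rdf$name[i] else rdf$id[i],
             lower_bound = rdf$lower_bound[i],
             upper_bound = rdf$upper_bound[i])
  })
  obj <- if ("objective" %in% names(rdf) && any(rdf$objective == 1)) {
    rdf$id[rdf$objective == 1][1]
  } else {
    hit <- grep("biomass", rdf$id, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) stop("table format error: no objective flagged")
    hit[1]
  }
  metabolic_model(mets, rxns, obj, version_tag = version_tag, id = model_id)
}
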