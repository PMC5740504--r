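# Model input/output.
#
# Two on-disk formats are supported:
#   * a JSON dialect ("metdriver-model-v1") used for toy models and all
#     shipped fixtures — explicit metabolite/reaction lists, per-reaction
#     stoichiometry maps, bounds and GPR strings;
#   * SBML Level 3 Version 1 with the FBC v2 extension, read with xml2.
#     The reader is scoped to the subset the writer emits plus the common
#     COBRA export layout (species/reactions, parameter-referenced flux
#     bounds, fbc gene-product associations, one active objective).
# Infinite bounds in either format are capped at +/-1000 flux units so the
# feasible region is always a bounded polytope.

MD_BOUND_CAP <- 1000

cap_bounds <- function(x, cap = MD_BOUND_CAP) {
  x[!is.finite(x) & x > 0] <- cap
  x[!is.finite(x) & x < 0] <- -cap
  pmin(pmax(x, -cap), cap)
}

#' Load a metabolic model from disk
#'
#' @param path file path.
#' @param format `"json"` (metdriver-model-v1 dialect) or `"sbml"`
#'   (Level 3 + FBC); defaults to guessing from the file extension.
#' @return a validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' @rdname load_model
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema) || !identical(doc$schema, "metdriver-model-v1")) {
    stop("not a metdriver-model-v1 file: ", path, call. = FALSE)
  }
  mets <- purrr::map_dfr(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in ", path, call. = FALSE)
    tibble::tibble(id = m$id,
                   compartment = m$compartment %||% "c")
  })
  rxns <- purrr::map_dfr(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in ", path, call. = FALSE)
    tibble::tibble(id = r$id,
                   lb = cap_bounds(as.numeric(r$lb %||% -MD_BOUND_CAP)),
                   ub = cap_bounds(as.numeric(r$ub %||% MD_BOUND_CAP)),
                   gpr = r$gpr %||% "")
  })
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  for (r in doc$reactions) {
    for (met in names(r$stoichiometry)) {
      if (!met %in% mets$id) {
        stop("reaction '", r$id, "' references undeclared metabolite '",
             met, "'", call. = FALSE)
      }
      S[met, r$id] <- as.numeric(r$stoichiometry[[met]])
    }
  }
  readouts <- if (!is.null(doc$readouts)) unlist(doc$readouts) else NULL
  metabolic_model(mets, rxns, S,
                  objective_id = doc$objective,
                  exchange_ids = as.character(unlist(doc$exchanges %||%
                                                       list())),
                  readouts = readouts)
}

#' Write a model to the JSON dialect
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  Sd <- as.matrix(model$S)
  rxns <- purrr::pmap(model$reactions, function(id, lb, ub, gpr, ...) {
    sto <- Sd[, id]
    sto <- sto[sto != 0]
    list(id = id, stoichiometry = as.list(sto), lb = lb, ub = ub, gpr = gpr)
  })
  doc <- list(
    schema = "metdriver-model-v1",
    metabolites = purrr::pmap(model$metabolites,
                              function(id, compartment, ...)
                                list(id = id, compartment = compartment)),
    reactions = rxns,
    objective = model$objective_id,
    exchanges = as.list(model$exchange_ids)
  )
  if (!is.null(model$readouts)) doc$readouts <- as.list(model$readouts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- SBML ------------------------------------------------------------------

# attribute lookup by local name (SBML extension attributes are
# namespace-prefixed, e.g. fbc:lowerFluxBound)
sbml_attr <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == local)
  if (length(hit)) unname(at[hit[1]]) else NA_character_
}

# element search by local name, ignoring namespaces
sbml_find_all <- function(node, ...) {
  path <- paste(vapply(c(...), function(p)
    paste0("*[local-name()='", p, "']"), character(1)), collapse = "/")
  xml2::xml_find_all(node, paste0(".//", path))
}

sbml_gpr_from_node <- function(node, labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gp <- sbml_attr(node, "geneProduct")
    return(labels[[gp]] %||% gp)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpr_from_node, character(1), labels = labels)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' @rdname load_model
#' @export
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparsable SBML: ", path, " (",
                                           conditionMessage(e), ")",
                                           call. = FALSE))
  species <- sbml_find_all(doc, "listOfSpecies", "species")
  boundary <- vapply(species, sbml_attr, character(1),
                     local = "boundaryCondition") %in% "true"
  mets <- tibble::tibble(
    id = xml2::xml_attr(species, "id"),
    compartment = dplyr::coalesce(xml2::xml_attr(species, "compartment"),
                                  "c")
  )[!boundary, ]
  params <- sbml_find_all(doc, "listOfParameters", "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  gps <- sbml_find_all(doc, "listOfGeneProducts", "geneProduct")
  gp_id <- vapply(gps, sbml_attr, character(1), local = "id")
  gp_label <- vapply(gps, sbml_attr, character(1), local = "label")
  labels <- as.list(stats::setNames(dplyr::coalesce(gp_label, gp_id),
                                    gp_id))
  rnodes <- sbml_find_all(doc, "listOfReactions", "reaction")
  if (length(rnodes) == 0) stop("SBML file has no reactions: ", path,
                                call. = FALSE)
  get_bound <- function(node, which, default) {
    ref <- sbml_attr(node, which)
    if (!is.na(ref) && ref %in% names(pvals)) return(pvals[[ref]])
    # fall back to plain attributes some exporters use
    raw <- sbml_attr(node, sub("FluxBound", "", which))
    if (!is.na(raw)) as.numeric(raw) else default
  }
  rows <- purrr::map(rnodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- get_bound(node, "lowerFluxBound",
                    if (rev) -MD_BOUND_CAP else 0)
    ub <- get_bound(node, "upperFluxBound", MD_BOUND_CAP)
    gpa <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']/*")
    gpr <- if (inherits(gpa, "xml_node")) sbml_gpr_from_node(gpa, labels)
           else ""
    sto <- list()
    for (sr in sbml_find_all(node, "listOfReactants",
                             "speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      sto[[sp]] <- (sto[[sp]] %||% 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    for (sr in sbml_find_all(node, "listOfProducts",
                             "speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      sto[[sp]] <- (sto[[sp]] %||% 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    list(id = id, lb = cap_bounds(lb), ub = cap_bounds(ub), gpr = gpr,
         sto = sto)
  })
  rxns <- purrr::map_dfr(rows, function(r)
    tibble::tibble(id = r$id, lb = r$lb, ub = r$ub, gpr = r$gpr))
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  for (r in rows) {
    for (sp in names(r$sto)) {
      if (sp %in% mets$id) S[sp, r$id] <- r$sto[[sp]]
    }
  }
  objs <- sbml_find_all(doc, "listOfObjectives", "objective",
                        "listOfFluxObjectives", "fluxObjective")
  if (length(objs) == 0) {
    stop("SBML file declares no flux objective: ", path, call. = FALSE)
  }
  objective_id <- sbml_attr(objs[[1]], "reaction")
  # exchanges: SBO-annotated boundary reactions when the file carries the
  # annotation, otherwise reactions touching exactly one metabolite
  sbo <- vapply(rnodes, sbml_attr, character(1), local = "sboTerm")
  if (any(sbo %in% "SBO:0000627")) {
    exchange_ids <- rxns$id[sbo %in% "SBO:0000627"]
  } else {
    n_touch <- Matrix::colSums(S != 0)
    exchange_ids <- rxns$id[n_touch == 1]
  }
  metabolic_model(mets, rxns, S, objective_id = objective_id,
                  exchange_ids = exchange_ids)
}

#' Write a model as SBML Level 3 + FBC v2
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  num <- function(x) formatC(x, digits = 17, format = "g")
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  con <- character()
  add <- function(...) con <<- c(con, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">')
  add('<model id="metdriver_model" fbc:strict="true">')
  comps <- unique(model$metabolites$compartment)
  add("<listOfCompartments>")
  for (cp in comps) {
    add('<compartment id="', sid(cp), '" constant="true"/>')
  }
  add("</listOfCompartments>")
  add("<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    add('<species id="', sid(model$metabolites$id[i]), '" compartment="',
        sid(model$metabolites$compartment[i]),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
        'constant="false"/>')
  }
  add("</listOfSpecies>")
  add("<listOfParameters>")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- sid(model$reactions$id[i])
    add('<parameter id="', rid, '_lb" value="', num(model$reactions$lb[i]),
        '" constant="true"/>')
    add('<parameter id="', rid, '_ub" value="', num(model$reactions$ub[i]),
        '" constant="true"/>')
  }
  add("</listOfParameters>")
  genes <- model_genes(model)
  if (length(genes)) {
    add("<fbc:listOfGeneProducts>")
    for (g in genes) {
      add('<fbc:geneProduct fbc:id="gp_', sid(g), '" fbc:label="', esc(g),
          '"/>')
    }
    add("</fbc:listOfGeneProducts>")
  }
  gpr_xml <- function(tree) {
    if (is.character(tree)) {
      return(paste0('<fbc:geneProductRef fbc:geneProduct="gp_', sid(tree),
                    '"/>'))
    }
    tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
    paste0("<", tag, ">",
           paste(vapply(tree$args, gpr_xml, character(1)), collapse = ""),
           "</", tag, ">")
  }
  Sd <- as.matrix(model$S)
  add("<listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    id <- model$reactions$id[i]; rid <- sid(id)
    sbo <- if (id %in% model$exchange_ids)
      ' sboTerm="SBO:0000627"' else ""
    add('<reaction id="', rid, '" reversible="',
        tolower(model$reactions$lb[i] < 0), '" fast="false"', sbo,
        ' fbc:lowerFluxBound="', rid, '_lb" fbc:upperFluxBound="', rid,
        '_ub">')
    tree <- model$gpr[[id]]
    if (!is.null(tree)) {
      add("<fbc:geneProductAssociation>", gpr_xml(tree),
          "</fbc:geneProductAssociation>")
    }
    sto <- Sd[, id]
    reac <- sto[sto < 0]; prod <- sto[sto > 0]
    if (length(reac)) {
      add("<listOfReactants>")
      for (sp in names(reac)) {
        add('<speciesReference species="', sid(sp), '" stoichiometry="',
            num(-reac[[sp]]), '" constant="true"/>')
      }
      add("</listOfReactants>")
    }
    if (length(prod)) {
      add("<listOfProducts>")
      for (sp in names(prod)) {
        add('<speciesReference species="', sid(sp), '" stoichiometry="',
            num(prod[[sp]]), '" constant="true"/>')
      }
      add("</listOfProducts>")
    }
    add("</reaction>")
  }
  add("</listOfReactions>")
  add('<fbc:listOfObjectives fbc:activeObjective="obj">')
  add('<fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('<fbc:listOfFluxObjectives>')
  add('<fbc:fluxObjective fbc:reaction="', sid(model$objective_id),
      '" fbc:coefficient="1"/>')
  add("</fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>")
  add("</model></sbml>")
  writeLines(con, path)
  invisible(path)
}

#' Read a medium from YAML
#'
#' Layout: `name:` plus `exchanges:` mapping exchange ids to
#' `[uptake, secretion]` bounds.
#'
#' @param path YAML file path.
#' @return an `md_media` object.
#' @export
read_media_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  bounds <- lapply(doc$exchanges, function(b) cap_bounds(as.numeric(b)))
  media(bounds, name = doc$name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
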