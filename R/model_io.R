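# Model readers and writers.
#
# Two on-disk dialects are supported:
#  * a JSON dialect mirroring the COBRA community schema
#    (id / metabolites / reactions with metabolites maps, bounds, subsystem,
#    gene_reaction_rule, objective_coefficient), so small Recon-derived
#    submodels can be dropped in unchanged;
#  * SBML Level 3 with the fbc package carrying bounds, objectives and
#    gene-product associations.

#' Load a metabolic model from disk
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; `"auto"` guesses from the extension.
#' @return a validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("format error: cannot parse JSON model '", path,
                             "': ", conditionMessage(e))
  )
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("format error: JSON model missing 'metabolites' or 'reactions' list")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("format error: metabolite without an 'id'")
    data.frame(id = m$id, name = m$name %||% "",
               compartment = m$compartment %||% "",
               hmdb_id = m$annotation$hmdb %||% (m$hmdb_id %||% ""),
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("format error: reaction without an 'id'")
    data.frame(id = r$id, name = r$name %||% "",
               lower_bound = as.numeric(r$lower_bound %||% -1000),
               upper_bound = as.numeric(r$upper_bound %||% 1000),
               subsystem = r$subsystem %||% "",
               gene_reaction_rule = r$gene_reaction_rule %||% "",
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) {
    coefs <- unlist(r$metabolites %||% list())
    if (is.null(coefs)) numeric(0) else coefs
  })
  names(stoich) <- rxns$id
  obj_coef <- vapply(doc$reactions,
                     function(r) as.numeric(r$objective_coefficient %||% 0),
                     numeric(1))
  objective <- NULL
  if (any(obj_coef != 0)) {
    objective <- list(reaction = rxns$id[which(obj_coef != 0)[1]],
                      direction = "max")
  }
  ann <- doc[setdiff(names(doc), c("metabolites", "reactions", "genes", "id"))]
  metabolic_model(mets, rxns, stoich, objective, annotations = ann,
                  id = doc$id %||% basename(path))
}

#' Write a metabolic model as COBRA-style JSON
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj_rxn <- if (is.null(model$objective)) "" else model$objective$reaction
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (nzchar(m$hmdb_id)) out$annotation <- list(hmdb = m$hmdb_id)
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      coefs <- model$stoichiometry[, i]
      coefs <- coefs[coefs != 0]
      list(id = r$id, name = r$name,
           metabolites = as.list(coefs),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           subsystem = r$subsystem,
           gene_reaction_rule = r$gene_reaction_rule,
           objective_coefficient = if (identical(r$id, obj_rxn)) 1 else 0)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

SBML_NS <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: cannot parse SBML '",
                                           path, "': ", conditionMessage(e)))
  model_node <- xml2::xml_find_first(doc, "//s:model", SBML_NS)
  if (inherits(model_node, "xml_missing")) {
    stop("format error: no <model> element in ", path)
  }

  params <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", SBML_NS)
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )

  specs <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", SBML_NS)
  boundary <- xml2::xml_attr(specs, "boundaryCondition")
  keep <- is.na(boundary) | boundary != "true"
  mets <- data.frame(
    id = xml2::xml_attr(specs, "id")[keep],
    name = ifelse(is.na(xml2::xml_attr(specs, "name")[keep]), "",
                  xml2::xml_attr(specs, "name")[keep]),
    compartment = ifelse(is.na(xml2::xml_attr(specs, "compartment")[keep]), "",
                         xml2::xml_attr(specs, "compartment")[keep]),
    hmdb_id = "",
    stringsAsFactors = FALSE
  )

  rxn_nodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", SBML_NS)
  if (!length(rxn_nodes)) stop("format error: SBML model has no reactions")
  rxns <- NULL
  stoich <- list()
  for (node in rxn_nodes) {
    rid <- xml2::xml_attr(node, "id")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    gpr <- sbml_gpr_text(xml2::xml_find_first(
      node, "./fbc:geneProductAssociation/*", SBML_NS))
    coefs <- numeric(0)
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", SBML_NS)) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(st)) st <- 1
      coefs[sp] <- (coefs[sp] %|na|% 0) - st
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", SBML_NS)) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(st)) st <- 1
      coefs[sp] <- (coefs[sp] %|na|% 0) + st
    }
    coefs <- coefs[names(coefs) %in% mets$id]  # boundary species fall away
    notes <- xml2::xml_find_first(
      node, ".//*[local-name()='p' and contains(text(),'SUBSYSTEM')]", SBML_NS)
    subsystem <- ""
    if (!inherits(notes, "xml_missing")) {
      subsystem <- sub("^\\s*SUBSYSTEM:\\s*", "", xml2::xml_text(notes))
    }
    rxns <- rbind(rxns, data.frame(
      id = rid, name = xml2::xml_attr(node, "name") %|na|% "",
      lower_bound = lb, upper_bound = ub, subsystem = subsystem,
      gene_reaction_rule = gpr, stringsAsFactors = FALSE))
    stoich[[rid]] <- coefs
  }

  obj_ref <- xml2::xml_find_first(
    doc, "//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    SBML_NS)
  objective <- NULL
  if (!inherits(obj_ref, "xml_missing")) {
    obj_node <- xml2::xml_find_first(doc, "//fbc:listOfObjectives/fbc:objective", SBML_NS)
    dir <- xml2::xml_attr(obj_node, "type")
    objective <- list(
      reaction = xml2::xml_attr(obj_ref, "reaction"),
      direction = if (identical(dir, "minimize")) "min" else "max"
    )
  }
  metabolic_model(mets, rxns, stoich, objective,
                  id = xml2::xml_attr(model_node, "id") %|na|% basename(path))
}

sbml_gpr_text <- function(node) {
  if (is.null(node) || inherits(node, "xml_missing")) return("")
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(xml2::xml_attr(node, "geneProduct"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpr_text, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Write a metabolic model as SBML Level 3 + fbc
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS[["s"]], '" xmlns:fbc="', SBML_NS[["fbc"]],
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$id), '" fbc:strict="true">'),
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "    <listOfSpecies>"
  )
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    comp <- if (nzchar(m$compartment)) m$compartment else "c"
    lines <- c(lines, paste0(
      '      <species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(comp),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  bound_ids <- character(0)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    for (side in c("lb", "ub")) {
      val <- if (side == "lb") r$lower_bound else r$upper_bound
      pid <- paste0(side, "_", r$id)
      bound_ids <- c(bound_ids, pid)
      lines <- c(lines, paste0(
        '      <parameter id="', esc(pid), '" value="', format(val, digits = 17),
        '" constant="true"/>'))
    }
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    coefs <- model$stoichiometry[, i]
    coefs <- coefs[coefs != 0]
    rev <- r$lower_bound < 0
    lines <- c(lines, paste0(
      '      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', if (rev) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="lb_', esc(r$id),
      '" fbc:upperFluxBound="ub_', esc(r$id), '">'))
    if (nzchar(r$subsystem)) {
      lines <- c(lines, paste0(
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: ',
        esc(r$subsystem), "</p></body></notes>"))
    }
    reactants <- coefs[coefs < 0]
    products <- coefs[coefs > 0]
    if (length(reactants)) {
      lines <- c(lines, "        <listOfReactants>")
      for (sp in names(reactants)) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', esc(sp), '" stoichiometry="',
          format(-reactants[[sp]], digits = 17), '" constant="true"/>'))
      }
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(products)) {
      lines <- c(lines, "        <listOfProducts>")
      for (sp in names(products)) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', esc(sp), '" stoichiometry="',
          format(products[[sp]], digits = 17), '" constant="true"/>'))
      }
      lines <- c(lines, "        </listOfProducts>")
    }
    if (nzchar(r$gene_reaction_rule)) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gpr_to_sbml(parse_gpr(r$gene_reaction_rule), indent = 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (!is.null(model$objective)) {
    dir <- if (identical(model$objective$direction, "min")) "minimize" else "maximize"
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      paste0('      <fbc:objective fbc:id="obj" fbc:type="', dir, '">'),
      "        <fbc:listOfFluxObjectives>",
      paste0('          <fbc:fluxObjective fbc:reaction="',
             esc(model$objective$reaction), '" fbc:coefficient="1"/>'),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

gpr_to_sbml <- function(ast, indent) {
  pad <- strrep(" ", indent)
  if (is.character(ast)) {
    return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="', ast, '"/>'))
  }
  tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
  c(paste0(pad, "<", tag, ">"),
    unlist(lapply(ast$args, gpr_to_sbml, indent = indent + 2)),
    paste0(pad, "</", tag, ">"))
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)
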