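# SBML Level 3 (fbc version 2) import/export, built on xml2.  Covers the
# subset of SBML used for flux-bounded stoichiometric models: compartments,
# species, bound parameters, reactions with species references, and an fbc
# objective.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_safe_id <- function(id) {
  # SBML SIds must start with a letter or underscore
  ifelse(grepl("^[A-Za-z_]", id), id, paste0("_", id))
}

sbml_restore_id <- function(sid) sub("^_(?=[0-9])", "", sid, perl = TRUE)

#' Write a network as SBML Level 3 with flux bounds
#'
#' @param net a `metabolic_network`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_sbml <- function(net, file) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('<model id="%s" fbc:strict="true">',
            gsub("[^A-Za-z0-9_]", "_", net$annotation$variant %||% "model")))
  comps <- unique(net$mets$compartment)
  lines <- c(lines, "<listOfCompartments>",
             sprintf('<compartment id="%s" constant="true"/>', comps),
             "</listOfCompartments>", "<listOfSpecies>")
  lines <- c(lines, sprintf(
    '<species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
    sbml_safe_id(net$mets$id), xml_escape(net$mets$name), net$mets$compartment,
    ifelse(nzchar(net$mets$formula),
           sprintf(' fbc:chemicalFormula="%s"', net$mets$formula), "")))
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  bnd <- sort(unique(c(net$rxns$lower_bound, net$rxns$upper_bound)))
  bnd_id <- stats::setNames(sprintf("bnd_%d", seq_along(bnd)),
                            sprintf("%.12g", bnd))
  lines <- c(lines, sprintf(
    '<parameter id="%s" value="%s" constant="true"/>',
    bnd_id, names(bnd_id)), "</listOfParameters>", "<listOfReactions>")
  for (i in seq_len(nrow(net$rxns))) {
    rid <- net$rxns$id[i]
    st <- reaction_stoichiometry(net, rid)
    lo <- bnd_id[[sprintf("%.12g", net$rxns$lower_bound[i])]]
    hi <- bnd_id[[sprintf("%.12g", net$rxns$upper_bound[i])]]
    lines <- c(lines, sprintf(
      '<reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      sbml_safe_id(rid), xml_escape(net$rxns$name[i]),
      tolower(net$rxns$lower_bound[i] < 0), lo, hi))
    sub <- st[st < 0]; prd <- st[st > 0]
    if (length(sub) > 0) {
      lines <- c(lines, "<listOfReactants>", sprintf(
        '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
        sbml_safe_id(names(sub)), -sub), "</listOfReactants>")
    }
    if (length(prd) > 0) {
      lines <- c(lines, "<listOfProducts>", sprintf(
        '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
        sbml_safe_id(names(prd)), prd), "</listOfProducts>")
    }
    lines <- c(lines, "</reaction>")
  }
  obj <- objective_id(net)
  lines <- c(lines, "</listOfReactions>")
  if (length(obj) == 1) {
    lines <- c(lines,
               '<fbc:listOfObjectives fbc:activeObjective="obj">',
               '<fbc:objective fbc:id="obj" fbc:type="maximize">',
               '<fbc:listOfFluxObjectives>',
               sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                       sbml_safe_id(obj)),
               '</fbc:listOfFluxObjectives>', '</fbc:objective>',
               '</fbc:listOfObjectives>')
  }
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, file)
  invisible(file)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Read an SBML Level 3 (fbc) model
#'
#' Parses the flux-bound subset of SBML written by [write_sbml()] (and by
#' common constraint-based tools): species, bound parameters, reactions
#' and the active fbc objective.
#'
#' @param file SBML file path.
#' @return a `metabolic_network`.
#' @export
read_sbml <- function(file) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model> element")
  sp <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (length(sp) == 0) stop("malformed SBML: no species")
  mets <- data.frame(
    id = sbml_restore_id(xml2::xml_attr(sp, "id")),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    formula = ifelse(is.na(xml2::xml_attr(sp, "chemicalFormula")), "",
                     xml2::xml_attr(sp, "chemicalFormula")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rx) == 0) stop("malformed SBML: no reactions")
  ids <- sbml_restore_id(xml2::xml_attr(rx, "id"))
  lob <- xml2::xml_attr(rx, "lowerFluxBound")
  upb <- xml2::xml_attr(rx, "upperFluxBound")
  if (anyNA(lob) || anyNA(upb)) {
    stop(sprintf("SBML reaction '%s' lacks flux bounds",
                 ids[which(is.na(lob) | is.na(upb))[1]]))
  }
  st <- lapply(rx, function(r) {
    reac <- xml2::xml_find_all(r, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(r, "./listOfProducts/speciesReference")
    v <- c(stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                           sbml_restore_id(xml2::xml_attr(reac, "species"))),
           stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                           sbml_restore_id(xml2::xml_attr(prod, "species"))))
    v[!is.na(v)]
  })
  names(st) <- ids
  obj_node <- xml2::xml_find_first(model, ".//*[local-name()='fluxObjective']")
  if (inherits(obj_node, "xml_missing")) stop("SBML model has no objective")
  obj_id <- sbml_restore_id(xml2::xml_attr(obj_node, "reaction"))
  rxns <- data.frame(
    id = ids,
    name = ifelse(is.na(xml2::xml_attr(rx, "name")), ids, xml2::xml_attr(rx, "name")),
    lower_bound = unname(parval[lob]),
    upper_bound = unname(parval[upb]),
    objective = ids == obj_id,
    stringsAsFactors = FALSE)
  metabolic_network(mets, rxns, st, annotation = list(
    model = xml2::xml_attr(model, "id"), variant = xml2::xml_attr(model, "id")))
}
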