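# Minimal SBML Level 3 (+ fbc) support: enough to round-trip stoichiometry,
# flux bounds and the active (biomass) objective of flux-balance models.

fbc_attr <- function(node, name) {
  v <- xml2::xml_attr(node, paste0("fbc:", name))
  if (is.na(v)) v <- xml2::xml_attr(node, name)
  v
}

#' Read an SBML Level 3 (fbc) model
#'
#' Parses species, reactions with stoichiometry, and fbc flux bounds.
#' Species flagged `boundaryCondition="true"` are dropped from the
#' stoichiometric matrix (they are outside the balanced system). The
#' biomass reaction defaults to the active fbc objective when not given.
#'
#' @inheritParams read_model
#' @return a validated `metabolic_network`
#' @export
read_sbml <- function(path, biomass = NULL, glucose = NULL, target = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) stop("no reactions found in SBML file: ", path)
  rxns <- xml2::xml_attr(rx_nodes, "id")
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  for (j in seq_along(rx_nodes)) {
    node <- rx_nodes[[j]]
    for (side in c(-1, 1)) {
      sel <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(node, paste0("./", sel, "/speciesReference"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        if (sp %in% mets) S[sp, j] <- S[sp, j] + side * coef
      }
    }
    lbid <- fbc_attr(node, "lowerFluxBound")
    ubid <- fbc_attr(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else
      if (xml2::xml_attr(node, "reversible") %in% "true") -1000 else 0
    ub[j] <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else 1000
  }

  if (is.null(biomass)) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) biomass <- fbc_attr(fo, "reaction")
  }
  if (is.null(biomass) || is.null(glucose) || is.null(target)) {
    stop("SBML model needs explicit biomass/glucose/target reaction ids ",
         "(biomass may come from the fbc active objective)")
  }
  metabolic_network(S, lb = lb, ub = ub, biomass = biomass,
                    glucose = glucose, target = target)
}

#' Write a network as SBML Level 3 with fbc bounds
#'
#' Emits one parameter per distinct bound value, reactant/product lists
#' from the sign of the stoichiometric coefficients, and an fbc maximize
#' objective on the biomass reaction.
#' @param net a `metabolic_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  vals <- sort(unique(c(net$lb, net$ub)))
  pid <- stats::setNames(paste0("fb_", seq_along(vals)),
                         sprintf("%.17g", vals))
  pref <- function(v) pid[[sprintf("%.17g", v)]]
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="momaknock_model" fbc:strict="true">',
    "<listOfParameters>",
    sprintf('<parameter id="%s" value="%s" constant="true"/>',
            pid, sprintf("%.17g", vals)),
    "</listOfParameters>",
    "<listOfCompartments>",
    '<compartment id="c" constant="true"/>',
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf(paste0('<species id="%s" compartment="c" constant="false" ',
                   'boundaryCondition="false" hasOnlySubstanceUnits="false"/>'),
            esc(net$metabolites)),
    "</listOfSpecies>",
    "<listOfReactions>")
  for (j in seq_along(net$reactions)) {
    col <- net$S[, j]
    rea <- which(col < 0); pro <- which(col > 0)
    out <- c(out, sprintf(
      paste0('<reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(net$reactions[j]), tolower(net$lb[j] < 0),
      pref(net$lb[j]), pref(net$ub[j])))
    if (length(rea)) {
      out <- c(out, "<listOfReactants>",
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       esc(net$metabolites[rea]), format(-col[rea], digits = 17)),
               "</listOfReactants>")
    }
    if (length(pro)) {
      out <- c(out, "<listOfProducts>",
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       esc(net$metabolites[pro]), format(col[pro], digits = 17)),
               "</listOfProducts>")
    }
    out <- c(out, "</reaction>")
  }
  out <- c(out,
    "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(net$biomass)),
    "</fbc:listOfFluxObjectives>",
    "</fbc:objective>",
    "</fbc:listOfObjectives>",
    "</model>",
    "</sbml>")
  writeLines(out, path)
  invisible(path)
}
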