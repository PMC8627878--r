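#' Read a typed graph from an SBML file
#'
#' Supports SBML Level 2 and Level 3 core models. Mapping: species become
#' substances (`boundaryCondition="true"` sets the boundary flag), reactions
#' become reaction nodes, `listOfReactants` entries become substrate edges,
#' `listOfProducts` product edges, and `listOfModifiers` regulator edges.
#' Modifier sign: `sboTerm="SBO:0000020"` or an `inhibition="true"` attribute
#' on the modifier reference maps to inhibition; SBO:0000021 or SBO:0000459
#' map to activation; anything else is `unknown` (SBML modifiers are unsigned
#' by default).
#'
#' First-order sink reactions tagged `sboTerm="SBO:0000179"` (degradation,
#' as written by [export_sbml()] for per-substance decay) are not structural
#' interactions and are skipped when building the typed graph.
#'
#' @param path SBML file.
#' @return a validated [typed_graph()].
#' @export
load_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing"))
    stop("file ", path, " has no <model> element (not SBML?)", call. = FALSE)

  sp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    is_boundary = tolower(xml2::xml_attr(sp_nodes, "boundaryCondition",
                                         default = "false")) == "true",
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L)
    stop("SBML model in ", path, " declares no reactions", call. = FALSE)

  rx_id <- xml2::xml_attr(rx_nodes, "id")
  rx_name <- xml2::xml_attr(rx_nodes, "name")
  rx_sbo <- xml2::xml_attr(rx_nodes, "sboTerm")
  keep <- is.na(rx_sbo) | rx_sbo != "SBO:0000179"
  if (!any(keep))
    stop("SBML model in ", path, " contains only degradation sinks",
         call. = FALSE)

  edges <- list()
  for (i in which(keep)) {
    rx <- rx_nodes[[i]]
    rid <- rx_id[i]
    refs <- function(list_name) {
      ns <- xml2::xml_find_all(rx, paste0(
        ".//*[local-name()='", list_name, "']/*"))
      ns
    }
    for (n in refs("listOfReactants")) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = xml2::xml_attr(n, "species"), target = rid,
        role = "substrate", sign = "unknown", stringsAsFactors = FALSE)
    }
    for (n in refs("listOfProducts")) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = rid, target = xml2::xml_attr(n, "species"),
        role = "product", sign = "unknown", stringsAsFactors = FALSE)
    }
    for (n in refs("listOfModifiers")) {
      sbo <- xml2::xml_attr(n, "sboTerm")
      inh <- tolower(xml2::xml_attr(n, "inhibition", default = "false"))
      sgn <- "unknown"
      if ((!is.na(sbo) && sbo == "SBO:0000020") || inh == "true") {
        sgn <- "inhibition"
      } else if (!is.na(sbo) && sbo %in% c("SBO:0000021", "SBO:0000459")) {
        sgn <- "activation"
      }
      edges[[length(edges) + 1L]] <- data.frame(
        source = xml2::xml_attr(n, "species"), target = rid,
        role = "regulator", sign = sgn, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else NULL
  # drop duplicate triples (repeated speciesReferences = stoichiometry > 1)
  if (!is.null(edges)) {
    edges <- edges[!duplicated(edges[c("source", "target", "role")]), ,
                   drop = FALSE]
  }
  typed_graph(substances = species,
              reactions = data.frame(id = rx_id[keep],
                                     name = rx_name[keep]),
              edges = edges)
}

# -- MathML helpers (SBML kinetic laws) --------------------------------------

mathml_ci <- function(x) paste0("<ci> ", x, " </ci>")
mathml_cn <- function(x) paste0("<cn> ", format(x, digits = 15), " </cn>")
mathml_apply <- function(op, ...) {
  paste0("<apply><", op, "/>", paste0(..., collapse = ""), "</apply>")
}

# rate-law MathML for one reaction of a contour model
rate_law_mathml <- function(law) {
  if (law$form == "hill_inhibited") {
    num <- c(mathml_ci("V"),
             vapply(law$boundary_factors, mathml_ci, character(1)))
    numerator <- if (length(num) > 1L)
      mathml_apply("times", paste0(num, collapse = "")) else num
    denom <- mathml_apply("plus", paste0(
      mathml_ci("K"),
      mathml_apply("power", paste0(mathml_ci(law$inhibitor), mathml_ci("h")))))
    mathml_apply("divide", paste0(numerator, denom))
  } else {
    fac <- c(mathml_ci(paste0("k_", law$reaction_id)),
             mathml_ci(law$substrate),
             vapply(law$boundary_factors, mathml_ci, character(1)))
    mathml_apply("times", paste0(fac, collapse = ""))
  }
}

#' Export a contour ODE model as SBML Level 3
#'
#' Writes an SBML Level 3 Version 1 document: one compartment, species with
#' initial concentrations (off-contour co-substrates/co-products flagged
#' `boundaryCondition="true"` and `constant="true"`), global parameters, and
#' the contour reactions with explicit MathML kinetic laws. The inhibitory
#' regulator is written as a modifier with `sboTerm="SBO:0000020"`.
#' Per-substance first-order degradation is written as one sink reaction per
#' state variable, tagged `sboTerm="SBO:0000179"`; [load_sbml()] skips these
#' when recovering the typed graph, so the round trip reproduces the
#' contour-induced subgraph.
#'
#' @param model an `ode_model` from [build_contour_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_sbml <- function(model, path) {
  if (!inherits(model, "contour_ode"))
    stop("export_sbml() expects a contour model from build_contour_model()",
         call. = FALSE)
  p <- model$parameters
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  sp_line <- function(id, name, conc, boundary) {
    sprintf(paste0('      <species id="%s" name="%s" compartment="cell" ',
                   'initialConcentration="%s" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="%s" constant="%s"/>'),
            esc(id), esc(name), format(conc, digits = 15),
            if (boundary) "true" else "false",
            if (boundary) "true" else "false")
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'level="3" version="1">'),
    sprintf('  <model id="%s" name="%s">', esc(model$sbml_id),
            esc(model$name)),
    '    <listOfCompartments>',
    paste0('      <compartment id="cell" size="1" spatialDimensions="3" ',
           'constant="true"/>'),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$state))) {
    s <- model$state[i, ]
    lines <- c(lines, sp_line(s$id, s$name, s$initial, FALSE))
  }
  for (i in seq_len(nrow(model$boundary))) {
    b <- model$boundary[i, ]
    lines <- c(lines, sp_line(b$id, b$name, b$conc, TRUE))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (nm in names(p)) {
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      esc(nm), format(p[[nm]], digits = 15)))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  math_open <- '<math xmlns="http://www.w3.org/1998/Math/MathML">'
  for (rx in model$reactions) {
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="false">',
      esc(rx$id), esc(rx$name)))
    if (length(rx$substrates) > 0L) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="1" constant="true"/>'),
                         esc(rx$substrates)),
                 '        </listOfReactants>')
    }
    if (length(rx$products) > 0L) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="1" constant="true"/>'),
                         esc(rx$products)),
                 '        </listOfProducts>')
    }
    if (length(rx$modifiers) > 0L) {
      lines <- c(lines, '        <listOfModifiers>',
                 sprintf(paste0('          <modifierSpeciesReference ',
                                'species="%s" sboTerm="SBO:0000020"/>'),
                         esc(rx$modifiers)),
                 '        </listOfModifiers>')
    }
    lines <- c(lines,
               '        <kineticLaw>',
               paste0('          ', math_open,
                      rate_law_mathml(rx$law), '</math>'),
               '        </kineticLaw>',
               '      </reaction>')
  }
  # degradation sinks, one per state variable
  for (i in seq_len(nrow(model$state))) {
    sid <- model$state$id[i]
    lines <- c(lines,
      sprintf(paste0('      <reaction id="deg_%s" name="degradation of %s" ',
                     'reversible="false" sboTerm="SBO:0000179">'),
              esc(sid), esc(sid)),
      '        <listOfReactants>',
      sprintf(paste0('          <speciesReference species="%s" ',
                     'stoichiometry="1" constant="true"/>'), esc(sid)),
      '        </listOfReactants>',
      '        <kineticLaw>',
      paste0('          ', math_open,
             mathml_apply("times", paste0(mathml_ci(paste0("kD_", sid)),
                                          mathml_ci(sid))),
             '</math>'),
      '        </kineticLaw>',
      '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write SBML to ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  writeLines(lines, con)
  close(con)
  # validate well-formedness
  xml2::read_xml(path)
  invisible(path)
}
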