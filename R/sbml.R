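# Minimal SBML Level-2 subset reader/writer (xml2). The subset is exactly
# what a pure mass-action model needs: species with initial amounts,
# reactions with integer stoichiometries, a reversible flag, and a kinetic
# law holding a single rate constant ("k"; "kf"/"kr" for reversible
# reactions). Compartments are treated as unit volume. Any construct
# outside the subset (events, rules, function definitions, other kinetic
# parameters) raises an error instead of being skipped, so a model that is
# not pure mass action can never be silently approximated.

sbml_ns <- function(doc) {
  ns <- xml2::xml_ns(doc)
  c(s = unname(ns[[1]]))
}

parse_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("malformed SBML: ", conditionMessage(e))))
  ns <- sbml_ns(doc)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) abort("malformed SBML: no <model> element")

  for (bad in c("listOfEvents", "listOfRules", "listOfFunctionDefinitions",
                "listOfConstraints", "listOfInitialAssignments")) {
    if (!inherits(xml2::xml_find_first(model, paste0("./s:", bad), ns), "xml_missing")) {
      abort(paste0("unsupported construct: <", bad, ">"))
    }
  }

  sp_nodes <- xml2::xml_find_all(model, "./s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) abort("malformed SBML: no species")
  species <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id")),
    initial_amount = as.numeric(dplyr::coalesce(
      xml2::xml_attr(sp_nodes, "initialAmount"),
      xml2::xml_attr(sp_nodes, "initialConcentration"), "0")),
    compartment = dplyr::coalesce(xml2::xml_attr(sp_nodes, "compartment"), "cell")
  )
  if (anyNA(species$id)) abort("malformed SBML: species without id")

  rx_nodes <- xml2::xml_find_all(model, "./s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) abort("malformed SBML: no reactions")
  rows <- lapply(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    reversible <- !identical(xml2::xml_attr(node, "reversible"), "false")
    side <- function(which) {
      refs <- xml2::xml_find_all(node, paste0("./s:", which, "/s:speciesReference"), ns)
      if (!length(refs)) return(setNames(numeric(0), character(0)))
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(dplyr::coalesce(xml2::xml_attr(refs, "stoichiometry"), "1"))
      if (any(!sp %in% species$id)) {
        abort(paste0("reaction ", id, ": unknown species ",
                     paste(setdiff(sp, species$id), collapse = ", ")))
      }
      setNames(st, sp)
    }
    kl <- xml2::xml_find_first(node, "./s:kineticLaw", ns)
    if (inherits(kl, "xml_missing")) {
      abort(paste0("reaction ", id, ": missing kineticLaw"))
    }
    pars <- xml2::xml_find_all(kl, "./s:listOfParameters/s:parameter", ns)
    pn <- xml2::xml_attr(pars, "id")
    pv <- as.numeric(xml2::xml_attr(pars, "value"))
    if (reversible) {
      if (!setequal(pn, c("kf", "kr"))) {
        abort(paste0("unsupported construct: reaction ", id,
                     " kineticLaw is not a reversible mass-action constant pair (kf, kr)"))
      }
      kf <- pv[pn == "kf"]; kr <- pv[pn == "kr"]
    } else {
      if (length(pn) != 1) {
        abort(paste0("unsupported construct: reaction ", id,
                     " kineticLaw is not a single mass-action constant"))
      }
      kf <- pv[1]; kr <- NA_real_
    }
    tibble(id = id, rate_constant = kf, rate_constant_rev = kr,
           reversible = reversible,
           reactants = list(side("listOfReactants")),
           products = list(side("listOfProducts")))
  })
  rxn_network(species, dplyr::bind_rows(rows))
}

write_network_sbml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="network">',
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  lines <- c(lines, sprintf(
    '      <species id="%s" name="%s" compartment="%s" initialAmount="%.17g"/>',
    esc(net$species$id), esc(net$species$name), esc(net$species$compartment),
    net$species$initial_amount))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  for (j in seq_len(nrow(net$reactions))) {
    r <- net$reactions[j, ]
    refs <- function(v, tag) {
      if (!length(v)) return(character(0))
      c(sprintf('        <%s>', tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%g"/>',
                names(v), unname(v)),
        sprintf('        </%s>', tag))
    }
    pars <- if (r$reversible) {
      sprintf('            <parameter id="%s" value="%.17g"/>',
              c("kf", "kr"), c(r$rate_constant, r$rate_constant_rev))
    } else {
      sprintf('            <parameter id="k" value="%.17g"/>', r$rate_constant)
    }
    lines <- c(lines,
               sprintf('      <reaction id="%s" reversible="%s">',
                       esc(r$id), tolower(r$reversible)),
               refs(r$reactants[[1]], "listOfReactants"),
               refs(r$products[[1]], "listOfProducts"),
               '        <kineticLaw>',
               '          <listOfParameters>',
               pars,
               '          </listOfParameters>',
               '        </kineticLaw>',
               '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
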