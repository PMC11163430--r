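# SBML Level 3 Version 2 export of a network with mass-action kinetic laws.
# Export-only convenience for interchange with external simulators.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

mathml_product <- function(k_id, side) {
  terms <- c(sprintf("<ci> %s </ci>", k_id),
             unlist(lapply(names(side), function(sp) {
               s <- side[[sp]]
               if (s == 1L) sprintf("<ci> %s </ci>", sbml_id(sp))
               else sprintf(paste0("<apply><power/><ci> %s </ci>",
                                   "<cn type=\"integer\"> %d </cn></apply>"),
                            sbml_id(sp), s)
             })))
  paste0("<apply><times/>", paste(terms, collapse = ""), "</apply>")
}

#' Export a network as an SBML document
#'
#' Writes an SBML Level 3 Version 2 model with one well-mixed compartment,
#' the species with their initial concentrations, and one reversible
#' reaction per network reaction whose kinetic law is the mass-action net
#' rate `k_f * prod(c^S-) - k_r * prod(c^S+)` with the derived rate
#' constants.  Deterministic for fixed input; export-only (no SBML import).
#'
#' @param net An [rn_network()].
#' @param params Parameter table.
#' @param settings [simulation_settings()] (supplies the temperature for
#'   the rate constants and initial concentrations).
#' @param path Output file.
#' @export
export_sbml <- function(net, params, settings, path) {
  rates <- derive_rates(net, params, settings$T)
  c0 <- vapply(net$species, `[[`, 0, "c0")
  if (!is.null(settings$c0)) c0[names(settings$c0)] <- settings$c0

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" ",
           "level=\"3\" version=\"2\">"),
    "  <model id=\"network\" substanceUnits=\"mole\" timeUnits=\"second\">",
    "    <listOfCompartments>",
    paste0("      <compartment id=\"batch\" spatialDimensions=\"3\" ",
           "size=\"1\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (sp in net$species) {
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"batch\" ",
             "initialConcentration=\"%.15g\" hasOnlySubstanceUnits=\"false\" ",
             "boundaryCondition=\"false\" constant=\"false\"/>"),
      sbml_id(sp$id), xml_escape(sp$id), c0[[sp$id]]))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    rid <- sbml_id(rx$id)
    lines <- c(lines, sprintf(
      "      <reaction id=\"%s\" reversible=\"true\">", rid),
      "        <listOfReactants>")
    for (sp in names(rx$lhs))
      lines <- c(lines, sprintf(
        paste0("          <speciesReference species=\"%s\" ",
               "stoichiometry=\"%d\" constant=\"true\"/>"),
        sbml_id(sp), rx$lhs[[sp]]))
    lines <- c(lines, "        </listOfReactants>", "        <listOfProducts>")
    for (sp in names(rx$rhs))
      lines <- c(lines, sprintf(
        paste0("          <speciesReference species=\"%s\" ",
               "stoichiometry=\"%d\" constant=\"true\"/>"),
        sbml_id(sp), rx$rhs[[sp]]))
    kf <- sprintf("kf_%s", rid); kr <- sprintf("kr_%s", rid)
    lines <- c(lines,
      "        </listOfProducts>",
      "        <kineticLaw>",
      "          <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
      paste0("            <apply><minus/>",
             mathml_product(kf, rx$lhs),
             mathml_product(kr, rx$rhs), "</apply>"),
      "          </math>",
      "          <listOfLocalParameters>",
      sprintf("            <localParameter id=\"%s\" value=\"%.15g\"/>",
              kf, rates$k_plus[[j]]),
      sprintf("            <localParameter id=\"%s\" value=\"%.15g\"/>",
              kr, rates$k_minus[[j]]),
      "          </listOfLocalParameters>",
      "        </kineticLaw>",
      "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
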