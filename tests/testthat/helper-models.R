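# SBML variants built in code for simulator and loader tests.

load_sbml_text <- function(text) {
  path <- tempfile("model_", fileext = ".xml")
  writeLines(text, path, useBytes = TRUE)
  on.exit(unlink(path))
  load_sbml_model(path)
}

# constant inflow: dX/dt = rate, no steady state
production_model_sbml <- function(rate = 1) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '  <model id="production">\n',
    '    <listOfCompartments><compartment id="compartment" size="1"/></listOfCompartments>\n',
    '    <listOfSpecies><species id="X" compartment="compartment" initialConcentration="0"/></listOfSpecies>\n',
    '    <listOfParameters><parameter id="v" value="', rate, '"/></listOfParameters>\n',
    '    <listOfReactions>\n',
    '      <reaction id="inflow" reversible="false">\n',
    '        <listOfProducts><speciesReference species="X"/></listOfProducts>\n',
    '        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>compartment</ci><ci>v</ci></apply></math></kineticLaw>\n',
    '      </reaction>\n',
    '    </listOfReactions>\n',
    '  </model>\n</sbml>\n')
}

# conversion model with an appended construct
conversion_with <- function(extra) {
  base <- petabkit:::conversion_model_sbml()
  sub("    <listOfReactions>",
      paste0(extra, "\n    <listOfReactions>"), base, fixed = TRUE)
}

event_snippet <- paste0(
  '    <listOfEvents><event id="e1"><trigger>',
  '<math xmlns="http://www.w3.org/1998/Math/MathML">',
  '<apply><gt/><csymbol definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol>',
  '<cn>5</cn></apply></math></trigger></event></listOfEvents>')

rule_snippet <- paste0(
  '    <listOfRules><assignmentRule variable="obs_total">',
  '<math xmlns="http://www.w3.org/1998/Math/MathML">',
  '<apply><plus/><ci>A</ci><ci>B</ci></apply></math>',
  '</assignmentRule></listOfRules>')

# conversion model with an extra parameter declared (rule target)
conversion_with_rule <- function() {
  txt <- petabkit:::conversion_model_sbml()
  txt <- sub('      <parameter id="k2" value="0.6"/>',
             paste0('      <parameter id="k2" value="0.6"/>\n',
                    '      <parameter id="obs_total" value="0" constant="false"/>'),
             txt, fixed = TRUE)
  sub("    <listOfReactions>",
      paste0(rule_snippet, "\n    <listOfReactions>"), txt, fixed = TRUE)
}
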