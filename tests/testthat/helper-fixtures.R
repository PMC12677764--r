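# Shared fixtures, cached per test run (generation is deterministic, so
# caching only saves time).

.fixture_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    val <- switch(name,
      decay1 = gen_decay_chain(1, 0.1),
      decay2 = gen_decay_chain(2, c(0.1, 0.25)),
      decay3 = gen_decay_chain(3, c(0.1, 0.3, 0.7)),
      net = gen_mass_action_network(5, 6, seed = 3),
      stiff = gen_stiff(),
      osc = gen_oscillator(),
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fixture_info <- function(archive) {
  parse_sbml_info(sedverify:::find_sbml_entries(archive)[[1]]$content)
}

fixture_doc <- function(archive) {
  parse_sedml(sedverify:::find_sedml_entry(archive)$content)
}

# a minimal run_result for comparator tests
fake_run <- function(engine, values, status = "succeeded",
                     labels = paste0("c", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  colnames(values) <- labels
  structure(list(engine = engine, status = status,
                 unsupported_tags = character(0),
                 reports = list(report1 = values),
                 column_labels = list(report1 = labels),
                 log = "", nsteps = 0L),
            class = "run_result")
}

# hand-written SBML snippets for feature-tag tests
sbml_with <- function(body, level = "3", version = "1") {
  ns <- if (level == "3") "http://www.sbml.org/sbml/level3/version1/core"
        else "http://www.sbml.org/sbml/level2/version4"
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="%s" level="%s" version="%s">
  <model id="m">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="cell" initialAmount="10"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="B" compartment="cell" initialAmount="0"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k" value="0.5" constant="true"/>
    </listOfParameters>
    %s
  </model>
</sbml>', ns, level, version, body)
}

simple_reaction <- '<listOfReactions>
  <reaction id="J1" reversible="false" fast="false">
    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
    <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><ci>k</ci><ci>A</ci></apply>
    </math></kineticLaw>
  </reaction>
</listOfReactions>'
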