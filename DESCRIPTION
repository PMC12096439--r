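Package: hormetica
Title: Biphasic (Hormetic) Dose-Response Modeling for Salt-Dependent Enzyme Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits skewed-Gaussian hormetic dose-response curves to enzyme
    rate data measured across salt concentrations, compares them with the
    Cedergreen hormesis model by adjusted R-squared, and extracts the
    biologically meaningful summaries (peak rate y_max, peak concentration M,
    fold-stimulation over the zero-salt baseline, inflection-point slopes and
    the stimulatory concentration range). Companion tools cover quadratic
    (ligand-depletion) binding isotherms for fluorescence titrations, binding
    free energies, counterion-condensation salt-dependence slopes, and the
    percent occupancy of ion sites on DNA. A synthetic-data generator with
    known ground truth supports parameter-recovery studies of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
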