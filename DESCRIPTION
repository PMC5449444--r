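Package: slowosc
Title: Slow-Oscillation Analysis of Cortical Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of cortical Up and Down states from extracellular
    local field potentials (LFP) by combining three Up-state fingerprints
    (slow-oscillation envelope, gamma-band variance envelope, and log-scaled
    multi-unit activity) with principal-component weighting, together with
    the downstream metrics used to characterize slow oscillations under
    anesthesia: oscillation frequency, state durations and cycle
    variability, absolute and relative population firing rate from logMUA,
    traveling-wave propagation speed across linear electrode arrays,
    per-state Welch spectra with 1/f power-excess peaks, and per-state
    sample entropy. Includes a synthetic multichannel LFP generator with
    known ground truth so that every stage of the pipeline is testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
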