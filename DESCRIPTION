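Package: soilpmb
Title: Targeted Quantification and Ecological Risk Assessment of
    Polymyxin B in Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the lipopeptide antibiotic polymyxin B
    in soil from targeted tandem mass spectrometry (MRM) data, and for
    assessing the ecological risk of the measured residues.  Provides a
    synthetic signal generator with known ground truth (Gaussian MRM
    chromatograms, matrix-matched calibration series, spike/recovery
    validation panels, dose-by-time soil concentration series), peak
    integration with signal-to-noise estimation, least-squares
    calibration and back-calculation, signal-to-noise based detection
    and quantification limits, a full analytical method validation panel
    (accuracy, precision, recovery, matrix effect, selectivity), soil
    dissipation kinetics (first-order DT50 and five-half-life
    elimination), and an equilibrium-partitioning risk-quotient chain
    from an aquatic predicted no-effect concentration to a three-tier
    soil risk classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
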