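Package: glycoMS
Title: Serum N-Glycome Profiling from Direct-Infusion Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass calculus and profiling toolkit for serum N-glycomics by
    direct-infusion ion-trap mass spectrometry. Computes exact masses,
    elemental formulas, isotopic distributions and sodiated/deprotonated
    ion m/z for permethylated and native glycans; processes centroided
    peak lists (total-ion-mapping windows, isotope-cluster collapse,
    charge-state summation, threshold filtering, internal-standard
    quantification); assigns monosaccharide compositions to multiply
    charged peaks; simulates exoglycosidase digestion of glycan
    topologies; predicts and scores MSn B-type fragments; and derives
    comparative structural-feature profiles (sialylation, di-sialic-acid
    caps, core fucosylation, O-acetylation ladders) across species. A
    ground-truthed synthetic-spectra generator emulating five fish-serum
    N-glycomes makes every pipeline stage testable without instrument
    data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
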