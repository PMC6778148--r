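Package: phagetools
Title: Phage-Display Monobody Engineering and Binding Biophysics Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for engineering paralog-selective binders by
    phage display of loop-diversified tenth fibronectin type III (10FN3)
    monobody scaffolds. Covers degenerate-codon (NNK) library design and exact
    diversity combinatorics; triage of Sanger-sequenced clones (orientation,
    reading frame, restriction-site and stop-codon filtering, loop extraction);
    clone clustering by Needleman-Wunsch similarity and Markov clustering
    (MCL); biopanning and phage-ELISA selection analytics; binding-model fits
    for single-cycle kinetics surface plasmon resonance (1:1 Langmuir),
    isothermal titration calorimetry (one set of identical sites),
    fluorescence polarization (depletion-corrected direct and exact
    competitive Ki), competitive pull-down (Cheng-Prusoff one-site Ki) and
    tethered-binder effective concentrations; and NMR chemical-shift
    perturbation epitope mapping. Includes seeded synthetic-data generators
    for every input class so all pipelines are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'align.R'
    'clone-qc.R'
    'cluster.R'
    'codons.R'
    'csp.R'
    'fixtures.R'
    'fp.R'
    'itc.R'
    'scaffold.R'
    'library-design.R'
    'phagetools-package.R'
    'report.R'
    'selection.R'
    'spr.R'
    'utils.R'
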