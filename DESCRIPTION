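Package: crystprop
Title: Dynamic Amino-Acid Characteristics for Protein Crystallization
    Propensity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores protein crystallization propensity from sequence using
    three dynamic amino-acid characteristics: the occupancy-based
    distribution probability of each residue type, the future composition
    projected through single-nucleotide codon mutation, and the
    predictability of adjacent amino-acid pairs. Provides AAIndex1-based
    constant-characteristic encodings as a benchmark, logistic-regression
    and single-hidden-layer neural-network classifiers, per-characteristic
    screening, delete-1 jackknife validation, ROC analysis, a Mann-Whitney
    comparison of predictable portions, a synthetic-dataset generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    nnet,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
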