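Package: seqelm
Title: Protein Superfamily Classification with Voting Ensembles of
    Extreme Learning Machines
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Alignment-free classification of protein sequences into
    superfamilies. Sequences are represented by 56-dimensional n-gram
    feature vectors (36 exchange-group 2-gram frequencies plus 20 residue
    1-gram frequencies) and classified by single-hidden-layer feedforward
    networks trained with the extreme learning machine (ELM), its optimally
    pruned variant (OP-ELM, combining multiresponse sparse regression
    neuron ranking with PRESS leave-one-out model selection), and
    majority-voting ensembles of either (V-ELM, VOP-ELM). Includes a
    synthetic superfamily sequence generator with PIR-like class imbalance
    presets and a repeated-trial experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Classification, Proteomics, SequenceMatching, Software
RoxygenNote: 7.3.3
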