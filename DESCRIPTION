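Package: ThermoRAAC
Title: Thermophilic Protein Recognition from Reduced Amino Acid Alphabet and
    Mixed Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies protein sequences as thermophilic or non-thermophilic
    from sequence-derived descriptors. Extracts a mixed feature set combining
    gapped dipeptide frequencies over a reduced amino acid alphabet (Susko
    19-letter or Dayhoff 6-class schemes), a 188-dimensional physicochemical
    descriptor (amino acid composition plus composition/transition/
    distribution blocks over eight property partitions), and auto-cross
    covariance features of numeric property traces. Redundancy is removed in
    three stages: rule-based Pearson correlation pruning, max-relevance
    max-distance (MRMD) ranking with accuracy-driven subset selection, and
    principal component truncation by cumulative explained-variance
    contribution. Classifiers (SVM, random forest, decision tree, naive
    Bayes) are evaluated under stratified k-fold cross-validation with
    sensitivity, specificity, accuracy and ROC reporting. A synthetic
    labelled-sequence generator with tunable compositional class separation
    supports end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    e1071,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ThermoRAAC-package.R'
    'alphabet.R'
    'featureMatrix.R'
    'dipeptide.R'
    'sequenceIO.R'
    'evaluate.R'
    'reduce.R'
    'mrmd.R'
    'pca.R'
    'physchem.R'
    'pipeline.R'
    'synthetic.R'
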