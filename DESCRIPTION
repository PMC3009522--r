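Package: mfge
Title: Multi-Filter Enhanced Genetic Ensemble Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid filter-wrapper gene selection for labelled expression
    matrices. Five filter algorithms (chi-squared, ReliefF, symmetrical
    uncertainty, information gain, gain ratio) score every gene; the scores
    are fused by softmax scaling into an integer-valued gene frequency map,
    which biases the initialization and mutation of a niched genetic
    algorithm whose fitness combines per-classifier balanced accuracy
    (blocking) with majority-voting balanced accuracy over a five-classifier
    ensemble. Gene subsets harvested over repeated genetic-ensemble
    iterations are ranked by selection frequency and evaluated with a
    stratified double (nested) cross-validation protocol. Includes a
    synthetic expression-data generator with planted differential genes for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    randomForest,
    class,
    e1071,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
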