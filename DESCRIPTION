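Package: armsig
Title: Arm-Wise Copy-Number Signatures and Mutation Associations in Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for arm-level somatic copy-number analysis of tumour
    cohorts. Reads TCGA-style SEG segment files, minimal MAF mutation calls
    and UCSC cytoBand centromere tables; converts segment means (log2
    ratios) to chromosomal copy number (CCN); filters segments by length
    percentile and probe support; projects segments onto chromosome arms to
    build a patients-by-arms CCN matrix; screens gene mutations against
    genome-wide ploidy change with Welch t-tests and Bonferroni correction;
    computes arm-pair correlations with permutation significance; extracts
    arm-ploidy signatures by non-negative matrix factorisation with
    consensus cophenetic rank selection; ranks genes by cosine distance of
    signature composition between mutated and wild-type patients and tests
    within-signature mutation enrichment by permutation; and predicts
    per-gene mutation status from arm profiles with random forests and
    other classifiers, reporting ROC AUC and permutation feature
    importance. A seeded synthetic-cohort generator with planted signatures
    and gene couplings provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    glmnet,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
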