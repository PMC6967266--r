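Package: hccpanel
Title: Cross-Cohort Consensus Biomarker Discovery for Hepatocellular Carcinoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Platform-independent discovery and evaluation of diagnostic
    gene panels for hepatocellular carcinoma from multi-cohort
    transcriptomics. Implements per-cohort differential expression
    (Welch t and paired Wilcoxon signed-rank tests with Bonferroni
    control), cross-cohort consensus vote counting to select core genes
    significant in at least 80 percent of cohorts, direction-aware
    single-gene threshold (decision stump) classifiers with the
    sensitivity/specificity/accuracy/MCC metric suite and AUROC,
    cross-validated shortlisting and wrapper backward feature
    elimination over six classifier families, external-cohort
    evaluation, and prognostic assessment by mean-expression
    dichotomization, Kaplan-Meier/log-rank and Cox proportional-hazards
    models. A seeded multi-cohort simulator with planted differential
    and prognostic genes provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    limma,
    glmnet,
    ranger,
    randomForest,
    e1071,
    class,
    data.table,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Classification,
    Survival, BiomedicalInformatics
RoxygenNote: 7.3.3
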