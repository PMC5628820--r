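Package: PrakritiML
Title: Phenotype Stratification of Ayurveda Constitution Types by Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised and supervised stratification of individuals into
    Ayurveda constitution types (Prakriti) from categorical questionnaire
    phenotypes. Provides a seeded generator of questionnaire-like cohorts with
    latent class structure, missingness-aware preprocessing (5 percent
    missingness filter, mode imputation, removal of non-varying traits),
    unsupervised random-forest proximity dissimilarities, partition-around-
    medoids clustering with silhouette-based selection of the cluster number
    and a column-permutation ("Savannah") null, classical multidimensional
    scaling, penalized multinomial classifiers (LASSO and elastic net via
    glmnet), Boruta-style shadow-feature selection with tuned random forests,
    cross-cohort validation on a harmonized feature set, and a two-stage
    classifier that separates extreme constitution types from non-extreme
    mixtures using the maxima of class-membership probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    randomForest,
    glmnet,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'aaa-classes.R'
    'aab-generics.R'
    'cohort-generate.R'
    'preprocess.R'
    'dissimilarity.R'
    'hungarian.R'
    'clustering.R'
    'encode.R'
    'split.R'
    'penalized.R'
    'boruta.R'
    'forest.R'
    'evaluate.R'
    'two-stage.R'
    'io.R'
    'pipeline.R'
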