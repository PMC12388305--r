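Package: sakesense
Title: Predicting Sake Sensory Scores from LC-MS Metabolome Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking untargeted LC-MS metabolome peak tables of
    Japanese sake to quantitative descriptive analysis (QDA) sensory panel
    scores. Provides peak-table quality filters (zero-maximum and replicate
    coefficient-of-variation), retention-time / mass-to-charge annotation
    against a compound library, box-whisker outlier removal and one-way
    ANOVA gating of panel data, UV scaling and PCA overviews, a
    single-response OPLS (orthogonal projections to latent structures)
    estimator with replicate-grouped cross-validation, permutation-based
    model validation, CV-ANOVA significance testing, signed VIPpred
    variable importance, and cross-dataset (cross-year) transfer
    validation with common-variable model reduction. A synthetic-data
    generator with known ground truth emulates the statistical structure
    of such studies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
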