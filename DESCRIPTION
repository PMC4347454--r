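Package: picalink
Title: Parallel Independent Component Analysis for Imaging-Genetics Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint decomposition of a subjects-by-voxels fractional
    anisotropy (FA) matrix and a subjects-by-SNPs genotype dosage matrix by
    parallel independent component analysis (P-ICA): two infomax ICA
    decompositions run side by side while a correlation-enhancement term
    strengthens the link between one pair of subject-loading columns.
    Includes SNP quality control (call rate, exact Hardy-Weinberg test in
    controls, minor-allele-frequency filtering, LD-based missing-call
    replacement, ancestry principal-component removal), diagnosis-based SNP
    pre-filtering, voxelwise site-effect regression, model-order selection
    by minimum description length and by run-to-run component consistency,
    covariate-adjusted pairing statistics with Bonferroni control,
    max-statistic permutation testing, k-fold reproducibility analysis, and
    a synthetic-cohort generator with a planted linked component pair for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
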