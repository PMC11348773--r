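Package: snpcascade
Title: Diagnostic SNP Panels and Hierarchical Cascade Classifiers for
    Population Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers small diagnostic SNP panels from dense 0/1/2 genotype
    matrices by iterative discriminant analysis of principal components
    (DAPC), and assigns unknown samples to populations with a hierarchical
    knowledge-base network of per-node discriminant classifiers built on a
    Ward dendrogram of the reference samples.  Includes genotype matrix and
    VCF input with GATK-style hard filtering, SVD imputation of missing
    genotypes, a Balding-Nichols genotype simulator with admixture, and a
    reference-frequency population assigner.  Tolerates missing loci at
    prediction time through node-local mean imputation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
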