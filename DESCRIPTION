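Package: epiblup
Title: Orthogonal Partitioning of Additive, Dominance and Epistatic
    Genomic Variance with GBLUP and Gibbs Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds orthogonal genomic relationship matrices for additive
    effects, dominance deviations, and pairwise epistatic interactions
    (additive-by-additive, additive-by-dominance, dominance-by-dominance)
    from SNP genotypes, using VanRaden-style centering, the natural and
    orthogonal interactions (NOIA) dominance coding under Hardy-Weinberg
    equilibrium, and trace-normalized Hadamard products. Variance
    components of repeated-record traits (such as litter size in pigs)
    are estimated by single-site Gibbs sampling of a mixed model that
    includes genomic inbreeding as a covariate for directional dominance,
    a permanent environmental effect, and scaled-inverse-chi-square
    variance priors. Includes GBLUP prediction at fixed variance
    components, forward (whole/partial) cross-validation with method-R
    statistics, DIC and effective-sample-size diagnostics, and a
    simulator of genotypes and phenotypes with known additive, dominance,
    epistatic, permanent-environmental and inbreeding-depression
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
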