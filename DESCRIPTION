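Package: breedid
Title: Breed Assignment from SNP Genotypes with Informative Marker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selection of breed-informative SNP markers by four statistics
    (average Euclidean distance of breed allele frequencies, per-SNP
    Weir-Cockerham FST, PCA eigenvector loadings, and partial least squares
    regression coefficients), multi-breed classification with six classifiers
    (KNN, nearest shrunken centroids, PLS-DA with softmax probabilities,
    random forest, and polynomial/radial SVM), rejection of unknown breeds and
    crossbreds by a probability threshold, repeated stratified
    cross-validation, and design of marker panels for chosen breed subsets.
    Includes PLINK 1 binary and VCF genotype I/O, SNP identifier
    normalisation and allele harmonisation against a reference panel, the
    standard QC filters, and a Balding-Nichols multi-breed genotype simulator
    for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
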