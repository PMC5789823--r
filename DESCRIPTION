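Package: wmhshape
Title: Shape and Location Features of White Matter Hyperintensities on Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies white matter hyperintensities (WMH) on brain MRI beyond
    total volume. Individual lesions are extracted from binary segmentation
    masks by 26-connected component labeling, converted to closed triangular
    surface meshes, and described by per-lesion three-dimensional shape
    features (surface area, eccentricity, three compactness measures,
    box-counting fractal dimension, and curvature-based shape index and
    curvedness) and location features (punctuate-deep versus non-punctuate
    classification by ventricle distance and lesion diameter, lobe
    assignment, per-voxel mean eccentricity maps). A cohort layer provides
    per-subject summaries, natural-log transforms, age- and sex-adjusted
    linear regression with unstandardized and standardized coefficients, and
    per-lobe chi-square and Mann-Whitney U comparisons. A synthetic phantom
    and cohort generator supplies geometrically known test data so the whole
    pipeline can be validated without patient images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
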