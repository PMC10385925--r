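Package: adrenomorph
Title: CT Volumetry, Morphometry and Reference Intervals for the Canine Adrenal Gland
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying adrenal gland size and attenuation from
    contrast-enhanced abdominal CT: slice-addition volumetry and 3D-ROI
    Hounsfield-unit statistics over binary segmentation masks, gland-frame
    caliper measurements (craniocaudal length, pole and isthmus height and
    width), the volume-to-aorta ratio (RVA), weight-class percentile
    reference intervals, and the accompanying cohort statistics (Shapiro-Wilk
    gated ANOVA with Ryan-Einot-Gabriel-Welsch multiple range grouping,
    nonparametric alternatives, paired side tests, Pearson correlation
    banding). A synthetic module generates voxel phantoms with analytic
    ground truth and allometrically scaled multi-breed cohorts so the whole
    pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
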