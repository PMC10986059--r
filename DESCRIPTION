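Package: chorovasc
Title: Choroidal Vascularity and Choriocapillaris Perfusion Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies choroidal vascularity from structural OCT B-scans and
    choriocapillaris perfusion from en-face OCT angiography, together with the
    repeated-measures statistics used in near-work cohort studies of myopic
    children and adults. Binarizes the segmented choroid band with a masked
    Niblack local threshold to obtain luminal, stromal and total choroidal
    areas, the choroidal vascularity index and subfoveal choroidal thickness
    over a 6-mm submacular region; computes the choriocapillaris flow-deficit
    percentage by an absolute 1.5-times-SD threshold in a 2.5-mm circle after
    shadow and projection-artifact compensation; adjusts lateral scale for
    ocular magnification from axial length. Ships a synthetic OCT/OCTA
    generator with pixel-level ground truth so the whole pipeline is testable
    without device data, plus change-score, repeated-measures ANOVA
    (Greenhouse-Geisser), axial-length-adjusted group contrasts and
    ICC/Bland-Altman repeatability tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    png,
    sandwich,
    lmtest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
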