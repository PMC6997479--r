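Package: renogram
Title: Split Renal Function and Drainage-Curve Analysis for Dynamic Renography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparative dynamic renography: digital
    renal phantoms pairing functional MR urography (fMRU) signal series with
    posterior-projection renal scintigraphy (DRS) count series under a shared
    ground truth; time-activity curve extraction, background correction and
    peak finding; split renal function by the area-under-the-curve and
    Rutland-Patlak methods, with volumetric combination of per-unit-volume
    uptake indices and segmented parenchymal volumes; three-pattern drainage
    classification (normal, borderline, accumulation) plus NORA, renal output
    efficiency and Tmax; and the method-agreement layer (Bland-Altman limits
    of agreement, Cohen's kappa with interpretation bands, contingency-table
    diagnostic effectiveness, Spearman correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    pracma,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
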