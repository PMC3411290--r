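Package: lymphorad
Title: Radiation Risk from CT and PET Imaging in Malignant Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cumulative organ-dose bookkeeping over CT and 18F-FDG PET
    imaging schedules in paediatric Hodgkin disease and adult diffuse
    large B-cell lymphoma, excess-relative-risk modelling of
    radiation-induced cancer mortality, and competing-hazard cohort life
    tables that combine background, radiation-induced and disease-related
    mortality.  The life tables yield the fraction of radiation-induced
    deaths, radiation- and disease-related reductions of life expectancy,
    and survival after diagnosis, with and without correction for
    disease-related mortality.  A synthetic-data module generates
    realistic European-like all-cause and site-specific cancer mortality
    tables so the full analysis runs without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
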