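Package: swirf
Title: Cohort Age-Structure Monitoring from Shortwave-Infrared Spectra
    Outlier Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the age structure of wild mosquito cohorts
    from shortwave-infrared (SWIR) cuticular absorbance spectra. Implements
    Standard Normal Variate scatter correction, per-wavelength Tukey-fence
    (1.5 IQR) outlier counting, the cohort spectra outlier fraction f,
    measurement-tolerance gating of pre- versus post-adulticide differences,
    a four-way trend-group classifier combining abundance and f trajectories,
    and the supporting series of simple linear regressions of f on study
    covariates. Ships the study's printed summary tables as plain-text
    fixtures and a synthetic SWIR spectra generator (age-dependent drift,
    multiplicative/additive scatter, duplicate scans, treatment
    kill/recruitment dynamics) so the whole pipeline runs and is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
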