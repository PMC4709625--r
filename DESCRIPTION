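Package: nirflow
Title: On-Line NIR Process Monitoring by PLS Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolkit for quantitative on-line near-infrared (NIR)
    monitoring of pharmaceutical batch processes such as water precipitation
    of botanical extracts. Provides a synthetic process-spectra generator
    (Beer-Lambert mixture spectra with baseline drift, multiplicative
    scatter, heteroscedastic water-band noise and detector saturation),
    the standard spectral pretreatments (Savitzky-Golay derivatives,
    straight line subtraction, vector normalization, SNV, multiplicative
    scatter correction, constant offset elimination), spectral region
    selection with saturation masking and correlation diagnostics, a NIPALS
    partial least squares regression core with leave-one-out
    cross-validated latent-variable selection, the usual figures of merit
    (R2, RMSEC, RMSECV, RMSEP, RSEC, RSEP, RPD), and an end-to-end workflow
    for pretreatment comparison, calibration and streaming prediction.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
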