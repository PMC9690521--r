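Package: soundscapeFCM
Title: Time-Frequency Analysis of Long-Term Acoustic Environment Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the acoustic environment from long-term
    passive acoustic monitoring datasets. Reads fixed-length WAV recordings
    with site/timestamp metadata, estimates per-recording power spectra,
    selects a data-driven frequency binning by scanning mean intra-bin
    variance and Shannon evenness over candidate bin counts, denoises per-bin
    power time series with truncated principal component analysis, removes
    upper-quantile outliers, and summarises each site by median power spectra
    with quantile bands, per-bin min-max normalised date-by-frequency
    spectrograms, and frequency correlation matrices (squared Pearson
    correlations between bin power time series). A deterministic synthetic
    soundscape simulator with band-limited scheduled sources provides ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
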