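Package: ftircascade
Type: Package
Title: Physics-Informed Cascade Restoration of Low-Scan FTIR Spectra
Version: 0.1.0
Authors@R: person("FTIR", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Denoising and baseline correction of low-scan Fourier transform
    infrared (FTIR) spectra. Implements a two-stage 1D encoder-decoder
    denoising cascade joined by a deterministic, invertible "physics bridge"
    (inverse normalization, SNIP baseline subtraction in the absorbance
    domain, re-normalization), a supervised-tuned Savitzky-Golay + SNIP
    benchmark, a paired low/high-quality synthetic spectrum generator, and a
    leave-one-sample-out evaluation suite with global (RMSE, MAE, spectral
    angle, Pearson correlation) and peak-aware (position error, height bias)
    fidelity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
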