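Package: RamanPAT
Title: Online FT-Raman Monitoring of Fermentations by PLSR Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolbox for turning time-resolved vibrational spectra
    (online FT-Raman of fermentation broth, at-line FTIR/FT-Raman of biomass)
    into real-time concentration profiles of carbon substrate, biomass, lipids
    and carotenoids. Provides S4 containers for spectral time series and
    offline reference measurements; the standard spectral pretreatments
    (rubber-band convex-hull baseline correction, Savitzky-Golay
    smoothing/derivatives, anchor-peak normalisation, extended multiplicative
    signal correction) composable into named preprocessing recipes; PLS1
    regression with one-sample-out cross-validation and RMSE-optimal component
    selection; and a seeded synthetic fermentation-spectra generator (logistic
    growth kinetics, Gaussian/Lorentzian band libraries, scatter/baseline/noise
    artifacts) so every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), signal, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
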