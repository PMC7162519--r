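Package: cointsim
Title: Johansen Cointegration Testing with Psychometric Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation tools for studying how the Johansen trace test and
    vector error correction modelling behave when bivariate time series are
    measured the way psychological and psychosomatic studies measure them:
    on coarse interval or ordinal rating scales, with missing measurement
    occasions, and with ceiling or floor effects. Provides generators for
    stationary, integrated and cointegrated bivariate systems with known
    parameters, psychometric degradation operators, a from-scratch maximum
    likelihood cointegration rank test (trace variant) with VECM parameter
    estimation, an augmented Dickey-Fuller unit-root test, and a Monte Carlo
    harness that scores misclassification rates and the accuracy of the
    estimated cointegrating parameter.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
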