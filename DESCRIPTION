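Package: ssemodes
Title: Spatio-Spectral Eigenmode Decomposition of Multichannel Oscillatory Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multivariate autoregressive (MVAR) models to multichannel
    oscillatory recordings and decomposes them into spatio-spectral
    eigenmodes: poles of the companion matrix carrying a peak frequency, a
    damping time and a rank-1 network (residue) structure. The modal
    partial-fraction form of the transfer function is exactly equivalent to
    the Fourier form when all modes are included, so individual resonances
    can be isolated from the superposition. Dynamically important modes are
    selected by a max-statistic permutation test on damping times, and the
    spatial variability of mode networks is summarised by PCA with
    split-half reliability. A pole-placement simulator generates ground
    truth oscillatory network recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
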