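Package: soflow
Title: Effective Connectivity of Sleep Slow Oscillations via Sliding-Window
    MVAR and Generalized Partial Directed Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-related effective-connectivity analysis of multichannel
    sleep EEG. Detects slow oscillations (SOs) with zero-crossing amplitude
    and duration criteria, fits sliding-window multivariate autoregressive
    (MVAR) models around each SO trough, quantifies directed information
    flow with generalized partial directed coherence (GPDC), resamples the
    flow quantifiers onto a fixed SO-phase grid via the Hilbert transform,
    clusters SOs into Global and Local types by Hamming-distance K-means on
    binary co-occurrence footprints, flags SO-spindle coupling, and runs the
    downstream inferential stage (mixed-effects models of flow peak heights,
    SO versus non-SO window comparisons, and distance-stratified regressions
    of behavioural improvement on flow). Includes a synthetic-data generator
    that plants all of these effects with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
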