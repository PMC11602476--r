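Package: megonset
Title: Onset-Latency Analysis of MEG Evoked Responses with Audiovisual
    Interaction Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating onset latencies of evoked responses in
    magnetoencephalography (MEG) sensor and source space. Implements
    trial-level artifact rejection, condition averaging, zero-phase
    low-pass filtering, planar-gradiometer amplitude combination,
    minimum-norm source estimation with dSPM noise normalization on a
    user-supplied leadfield, a baseline-noise threshold onset detector
    with minimum-latency and sustain criteria, bootstrap onset
    distributions, audiovisual interaction contrasts AV-(A+V),
    cross-modal latency arithmetic (conduction delays, convergence and
    interaction lags), temporal-searchlight decoding with FDR-corrected
    significance curves, and a synthetic-session generator with known
    ground-truth onsets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
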