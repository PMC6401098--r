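Package: firmvpa
Title: Time-Resolved Decoding of Voluntary Imagery from fMRI Beta Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decode the content and strength of voluntary visual
    imagery from fMRI activity around a self-paced decision. Implements
    high-pass filtering and finite-impulse-response (FIR) response
    estimation, leave-one-run-out linear support-vector-machine decoding of
    beta series, perception-to-imagery cross-classification, searchlight
    information mapping with sign-flip cluster inference, permutation-based
    null ensembles with family-wise error control over time points,
    phase-encoded retinotopic mapping, and binocular-rivalry priming
    analyses. A synthetic BOLD generator with full ground truth makes every
    stage of the pipeline verifiable by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
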