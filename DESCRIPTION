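Package: gazeloop
Title: Nested Feedback Decomposition for Fly Gaze Stabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for unraveling nested sensory feedback loops in insect gaze
    stabilization. Provides velocity-normalized visual perturbation design,
    a closed-loop linear-time-invariant simulator of head and body responses
    (body-free, body-fixed, and motor-replay paradigms, with neck-joint
    saturation and sensory delays), non-parametric frequency-domain system
    identification by chirp-z spectral analysis (gain, phase, coherence,
    compensation error, saturation-corrected least-squares spectral analysis,
    circular statistics across animals, Monte Carlo uncertainty propagation),
    closed-loop feedback-decomposition algebra that isolates visual from
    nested mechanosensory contributions to head control, and detection and
    exponential-damping analysis of head saccades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
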