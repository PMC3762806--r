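Package: retmap
Title: Return-Map Segmentation and State-Transition Analysis of Dyadic
    Interaction Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes oscillatory interpersonal-distance time series from
    two-agent position recordings (e.g., motion capture of competitive
    martial-arts bouts).  Builds a composite state variable from the
    filtered distance and its delayed difference, detects peak-to-peak
    amplitude sequences per scene, fits moving windows on the return map
    (y[n], y[n+1]) to linear, exponential, and logarithmic one-dimensional
    maps with chi-square screening, classifies accepted segments as
    asymptotic/rotational attractors or repellers or intermittency, and
    estimates second- and third-order Markov transition statistics between
    discrete far/near states with Fisher exact group contrasts.  Includes a
    synthetic-data generator that plants known return-map regimes in
    continuous two-agent trajectories so every stage is verifiable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
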