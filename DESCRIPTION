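Package: mixbiotic
Title: Mixbiotic Society Measures for Temporal Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Dynamic communication-pattern statistics for temporal contact and
    message networks. Represents per-time communication as multidimensional
    activation vectors and summarises their step-to-step dynamics (information
    change, normalised and relative Euclidean distance, cosine similarity) into
    four community-phase measures: mobism (in-group crowding), atomism (social
    isolation), mixism (the balanced, "well-going" intermediate) and nihilism
    (near silence). Includes readers for common contact-list dialects
    (SocioPatterns and network-repository edge lists), a static graph-feature
    baseline, polar communication trajectories, radar-chart normalisation, a
    seeded synthetic regime generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
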