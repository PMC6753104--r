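Package: netcomm
Title: Send-Receive Communication Asymmetry in Weighted Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decentralized network communication measures (greedy spatial
    navigation, random-walk diffusion efficiency, search information and
    shortest-path efficiency) for weighted, spatially embedded connectomes,
    together with a cohort-level statistical framework for send-receive
    communication asymmetry: pairwise and regional one-sample tests with
    multiple-comparison correction, sender/receiver/neutral role
    classification, subsystem downsampling, normalized asymmetry indices for
    directed networks, degree- and cost-preserving null models, and seeded
    synthetic-data generators for spatially embedded cohorts with planted
    directionality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
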