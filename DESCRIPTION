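Package: midas
Title: Non-Targeted Mass-Isotopolome Analysis of Stable Isotope Labeling Data
Version: 0.1.0
Authors@R:
    person("MIDAS", "Developers", email = "midas@example.org", role = c("aut", "cre"))
Description: Tools for non-targeted analysis of mass isotopomer distributions
    (MIDs) from stable isotope labeling experiments. Provides quality-control
    filtering of fragment MIDs, ranking of putative metabolic flux changes by
    cross-condition mass-isotopomer abundance variation, Needleman-Wunsch
    alignment and Canberra-distance MID similarity networks for pathway
    contextualization of unidentified compounds, convolution-based
    deconvolution of moiety MIDs by weighted nonnegative least squares,
    natural isotope abundance correction, and an exact positional-isotopomer
    simulator of tracer propagation through small metabolic networks that
    generates ground-truth datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
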