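Package: mstconnect
Title: Minimum Spanning Tree Analysis of Wavelet-Coherence Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for group comparisons of resting-state
    functional brain networks: band-limited multivariate signal simulation with
    controllable coherence strength and hub topology, motion quality control,
    scale-4 MODWT wavelet coherence connectivity (Welch's overlapped averaged
    periodogram), minimum spanning tree backbone extraction with global
    (strength, diameter, kappa, leaf fraction) and nodal (degree, betweenness)
    metrics, and group-level inference via covariate-adjusted ANCOVA with
    Benjamini-Hochberg FDR control, LSD post-hoc contrasts, and max-statistic
    permutation tests with family-wise error control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
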