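Package: mela
Title: Energy Landscape Analysis of Time-Series Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduces genus-level 16S abundance profiles to co-occurring
    microbial assemblages with a latent Dirichlet allocation model, converts
    per-class assemblage abundances to binary (+1/-1) occurrence states by an
    upper-quartile rule, fits an exact pairwise maximum-entropy (Ising) model
    per disease class by moment-matching gradient ascent over all 2^I
    assemblage patterns, and constructs the resulting energy landscape:
    pattern energies, steepest-descent transition links, local minimal
    patterns and their attractor basins. Includes a Dirichlet-multinomial
    cohort simulator so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
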