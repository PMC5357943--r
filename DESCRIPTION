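Package: switchnet
Title: Switch-Gene Detection in Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Pearson-correlation gene co-expression networks from
    two-condition expression matrices, partitions genes into communities with
    the correlation distance d = 1 - r, computes network cartography
    statistics (participation coefficient, within-module degree,
    clusterphobic coefficient, global within-module degree), classifies hubs
    by the average Pearson correlation with their neighbours (date, party and
    fight-club hubs), and calls switch genes: outward-oriented,
    anti-correlated connectors in region R4 of the heat cartography map.
    Includes targeted-attack robustness curves, Kaplan-Meier/log-rank
    prioritisation of switch genes, Hamming-distance comparison of switch
    sets across datasets, Fisher over-representation analysis, and synthetic
    data generators with planted modules and switch nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    ape,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
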