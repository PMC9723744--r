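Package: myconet
Title: Mycelial Network Phenotyping from Images and Edge Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Translates images of fungal mycelia, or pre-extracted edge
    lists, into spatially embedded weighted graphs and computes a panel of
    fifteen morphological and network traits: hyphal dimensions, branching
    angle, length density, meshedness, transport efficiencies under a
    Poiseuille-style resistance model, construction cost relative to the
    minimum spanning tree, and robustness of root connectivity under five
    fungivory-style edge-removal attacks. Trait tables are analysed by
    partial redundancy analysis with permutation tests and by Pareto-front
    archetype identification in ordination space. Includes a seeded
    generator of synthetic foraging mycelia spanning sparse "guerrilla" to
    densely cross-linked "phalanx" phenotypes, with an image renderer, so
    the whole extraction pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    readxl,
    optparse,
    png,
    tiff,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
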