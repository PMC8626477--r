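Package: corescaffold
Title: Quantitative Structural Analysis of Hollow Multienzyme Core Scaffolds
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative cryo-EM and modelling analyses used to
    characterise hollow icosahedral multienzyme cores such as the pyruvate
    dehydrogenase complex (PDHc) E2/E3BP scaffold: contour-sweep density
    enclosure statistics for flexible elements, map-model cross-correlation,
    inter-subunit anchor distance grouping, interior volumetric occupancy
    inside a spherical mask, interface characterisation (buried surface area,
    contacts, simplified energy decomposition), distance-restraint pose
    screening, Michaelis-Menten kinetics, and alignment-column conservation.
    Includes synthetic generators (toy assemblies, simulated maps with planted
    flexible-element occupancy, disordered-chain ensembles, kinetics tables,
    alignments) so every stage is testable without external data, plus
    readers and writers for PDB, mmCIF and MRC/CCP4 2014 formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
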