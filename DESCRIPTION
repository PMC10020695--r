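Package: lexturn
Title: Beta-Turn Geometry and Autoproteolysis Kinetics of the LexA
    Cleavage Site Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two quantitative analyses behind small-molecule
    inhibition of LexA self-cleavage: geometric detection and classification
    of beta-turns in the cleavage site region from backbone coordinates
    (torsion computation, distance criteria, hydrogen-bond geometry), and a
    first-order autoproteolysis kinetics model that estimates per-condition
    cleavage rate constants from densitometry time courses, fits an
    inhibitor effectiveness parameter across inhibitor:protein ratios, and
    converts it to a dissociation constant. Includes seeded synthetic-data
    generators (cleavage time courses, peptide backbones built from
    prescribed torsions, toy screening tables), Kyte-Doolittle hydropathy
    profiling, and screening hit-rate bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
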