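Package: pyrescore
Title: Rubisco Small-Subunit Helix Hydrophobicity and Pyrenoid Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the surface hydrophobicity of the two alpha-helices (A and
    B) of the Rubisco small subunit (RBCS) and relates it to the presence or
    absence of the pyrenoid, the algal CO2-concentrating microcompartment.
    Maps RBCS homologs onto the Chlamydomonas reinhardtii reference numbering
    by pairwise alignment, extracts the 27 helix residues (reference positions
    68-80 and 131-144), masks six solvent-buried positions, and sums
    Kyte-Doolittle hydropathy over the 21 exposed positions. Provides a
    Brunner-Munzel rank test with a permutation fallback for fully separated
    groups, Fitch parsimony counting of trait-loss events on a species tree,
    a Sanger clone-consensus filter, a Shrake-Rupley solvent-accessible
    surface area engine for recomputing the buried-position mask from a
    structure, and seeded generators for synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
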