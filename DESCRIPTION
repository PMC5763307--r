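Package: ptm3d
Title: Structural Characterization of Post-Translational Modification Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps experimentally verified post-translational modification (PTM)
    sites onto protein three-dimensional structures by exact peptide identity and
    characterizes each mapped site by five structural properties: spatial
    amino-acid composition over 2-12 Angstrom radii, side-chain orientation
    angles of spatially neighboring residues, three-state secondary structure,
    division of acidic and basic neighbors, and solvent-accessible surface area.
    Classifies sites by proximity to bound small-molecule ligands (strong/weak
    association) and by location on domain-domain interaction interfaces using
    typed residue-contact criteria. Ships deterministic synthetic-structure
    builders (helices, strand pairs, engineered interfaces and ligand complexes)
    and a command-line pipeline producing per-site reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
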