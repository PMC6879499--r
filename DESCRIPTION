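Package: deepscreen
Title: Multi-Dimensional Network-Based Compound Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deep screening of small-molecule compounds along three
    progressively deeper biological axes. Compounds are clustered by
    structural similarity (maximum common substructure overlap
    coefficients or hashed circular fingerprints), by their docking-score
    profiles across a protein panel, and by degree-weighted network-effect
    profiles that combine rank-normalized docking scores with
    protein-protein interaction network topology. Each axis is clustered
    hierarchically with multiscale-bootstrap approximately unbiased (AU)
    support values, and the three dendrograms are compared so that
    compounds with similar or divergent system-level effects surface.
    Includes readers for SDF/MOL/SMILES structures, docking-score
    matrices and STRING-style interaction exports, a synthetic fixture
    generator with planted cluster structure, and an end-to-end pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ChemmineR,
    ChemmineOB,
    igraph,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
biocViews: Cheminformatics, Clustering, Network, GraphAndNetwork
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'clustering.R'
    'compare.R'
    'compounds.R'
    'docking.R'
    'fingerprint.R'
    'fixtures.R'
    'mcs.R'
    'molgraph.R'
    'pipeline.R'
    'ppi.R'
    'similarity.R'
    'zzz.R'
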