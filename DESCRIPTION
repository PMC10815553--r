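Package: gpcrdyn
Title: Activation Descriptors, Dynamical Network Paths and Interaction-Energy
    Post-Processing for GPCR Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for G-protein-coupled receptor
    (GPCR) ligand complexes. Computes trajectory stability metrics (RMSD,
    RMSF) and activation-state geometric descriptors for the conserved
    class-A microswitches (ligand-binding-site tightening, NPxxY, P-I-F,
    E/DRY), reduces them to fixed-length block medians and classifies blocks
    against active/inactive reference regions; builds residue-ligand
    dynamical networks from correlated Calpha motions and enumerates optimal
    and suboptimal communication pathways between the ligand and the
    G-protein binding site; and post-processes per-residue pair interaction
    energy decomposition (PIEDA) tables into polarity shares,
    attractive/repulsive calls, cross-complex heat maps and
    agonist-vs-antagonist binding-site occupancy comparisons. Ships seeded
    synthetic-data generators (trajectories with planted correlation
    structure and motif geometries, PIEDA tables with controlled component
    mixtures) so the full pipeline is testable without simulation engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'bw-mapping.R'
    'gpcrdyn-package.R'
    'io-tables.R'
    'io-trajectory.R'
    'methods-accessors.R'
    'network.R'
    'paths.R'
    'pieda.R'
    'trajectory-metrics.R'
    'pipeline.R'
    'synthetic.R'
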