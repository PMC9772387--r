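Package: clrescore
Title: Covalent-Labeling Guided Rescoring of Docked Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts differential covalent-labeling mass spectrometry data
    (per-residue degrees of modification in the unbound and bound states of a
    protein complex) into interface-distance restraints and uses them to
    rescore ensembles of docked protein-protein models. A calibrated linear
    model relates the percent change in modification upon binding to the
    shortest heavy-atom distance between a labeled residue and its docking
    partner; each docked model is penalized through a sigmoidal function of
    the deviation between observed and model-implied modification changes,
    penalties are summed over labeled residues, max-normalized across the
    ensemble, weighted, and added to an externally supplied interface energy
    to produce the combined score used for ranking. Includes alpha-carbon
    Kabsch RMSD evaluation against a reference complex, interface-agreement
    diagnostics, and a deterministic synthetic benchmark generator (toy
    two-chain complexes, rigid-body decoy ensembles, simulated labeling
    tables, and surrogate interface scores).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
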