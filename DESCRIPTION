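Package: apoflex
Title: Apo Versus Holo Protein Flexibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation and analysis pipeline for comparing backbone and
    side-chain flexibility within and between apo (ligand-free) and holo
    (ligand-bound) protein crystal structures. Builds families of
    sequence-identical structures, derives unified binding sites from
    ligand contacts at a distance cutoff, quantifies backbone flexibility
    as family-wise maximum C-alpha RMSD per pairing class (apo-apo,
    holo-holo, apo-holo), quantifies side-chain flexibility as minimal
    circular chi1-angle ranges per structure set, computes Shrake-Rupley
    solvent accessible surface areas of binding-site residues, and
    summarises the results with paired nonparametric tests and jackknife
    confidence bands. Includes a synthetic-structure generator with
    exactly known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
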