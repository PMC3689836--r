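Package: otomorph
Title: Comparative Morphometrics of the Mammalian Bony Labyrinth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of inner-ear (bony labyrinth)
    endocast measurements across placental mammals and their therian
    relatives.  Provides derived morphometric indices (semicircular-canal
    arc radius of curvature, angular deviation from the canal plane,
    cochlear coiling and spire aspect ratio, volumetric contributions),
    geometric measurement operators over 3D centerlines (total-least-squares
    plane fitting, arc extents, planarity deviation, inter-canal plane
    angles, spiral coiling, sagittal labyrinthine index), a parametric
    synthetic-labyrinth generator with known ground truth, log-log
    allometric scaling of labyrinth dimensions against body mass with
    body-mass prediction for fossil taxa, an aquatic-versus-terrestrial
    contrast of vestibular volume contributions, and ancestral-state
    reconstruction of discrete (parsimony) and continuous (Brownian-motion
    generalized least squares) labyrinth characters on a composite therian
    phylogeny.  Ships transcribed per-taxon measurement fixtures and the
    composite cladogram used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
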