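Package: craniostrain
Title: Masticatory Muscle-Force Optimization and Cranial Finite-Element
    Strain Analysis on Synthetic Skull Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated desk-scale pipeline for masticatory biomechanics:
    parametric generation of labelled tetrahedral cranium phantoms (bone,
    teeth, periodontal ligament, pulp and suture volumes, fenestrated lateral
    walls, mirror symmetry, named landmarks), inverse-dynamics simulation of
    incisor and molar bite cycles on a rigid mandible with muscle-strand
    activations found by per-instant quadratic optimization, multi-material
    linear-elastic finite-element solves of the cranium under each bite's
    nodal muscle loads with truss link elements for wrapped muscles, and
    multi-bite post-processing into cumulative peak von Mises strain tables,
    bite-mode and principal-strain dominance maps, strain histograms,
    mechanostat band volume fractions and soft-tissue sensitivity
    comparisons. Mesh input/output in Gmsh MSH, VTK VTU and Abaqus INP
    formats.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
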