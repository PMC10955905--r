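Package: fenplan
Title: Automated Fenestration Planning for Physician-Modified Endografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric planning of fenestrated endovascular aneurysm repair
    (FEVAR) on commercially available stent grafts. Given an aortic lumen
    segmentation (or centerline) and the ostia of the visceral vessels, the
    package flattens a parametric graft template into a 2D strut mask,
    measures each fenestration's arclength (AL) and proximal graft distance
    (PGD), searches all rotational/axial graft alignments for strut-free
    fenestration placements (with a bounded posterior relaxation for the
    renal arteries), lofts a deployed-graft triangle mesh along the aortic
    centerline, flattens it to a rectangle with a cotangent-weight Laplacian
    harmonic embedding, and maps the chosen 2D design back onto the 3D graft
    surface with barycentric texture mapping.  Outputs are operating-room
    modification instructions (CSV + diagram) and a textured surface mesh.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
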