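Package: vesselreg
Title: Vascular Centerline Graph Registration via Network Saliency and
    Circuit Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Registers pairs of vessel centerline graphs (2D retinal or 3D
    angiographic skeletons with per-node radii) without touching the raster
    images. Structurally salient bifurcations are detected and paired with a
    degree- and radius-weighted Network Structure Index, the graphs are
    decomposed into salient-free branches which are matched by sequential
    geometric criteria (forward direction, summed radius, tortuosity), and
    each branch is converted to a phasor circuit whose integrated voltage
    sequence drives node-level correspondence and fusion of the two graphs.
    Includes SWC and JSON graph readers/writers, a ground-truthed synthetic
    vascular tree generator with smooth non-linear deformation, and an
    evaluation harness for registration error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'vessel-graph.R'
    'nsi.R'
    'decomposition.R'
    'branch-matching.R'
    'circuit.R'
    'node-matching.R'
    'fusion.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
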