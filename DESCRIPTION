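Package: toothfem
Title: Finite Element Simulation of Occlusal Loading and Cervical Stress in Worn Teeth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying how occlusal wear changes the stress state of
    a lower second premolar, the mechanics behind non-carious cervical lesions
    (abfraction). Generates parametric multi-tissue tooth models (enamel, dentine,
    pulp, periodontal ligament, alveolar bone) at prescribed wear stages, detects
    occlusal contact patches against an antagonist surface, converts patches into
    facet-perpendicular loads normalized to a prescribed resultant (default 100 N),
    solves the linear-elastic problem on 10-node tetrahedra, and compares maximum
    principal (tensile) stress at homologous buccal-cervical nodes across wear
    states. Includes canonical verification solids (bar, cantilever, cube), STL/PLY
    and VTK/VTU readers and writers, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    xml2,
    graphics,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
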