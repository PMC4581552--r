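Package: cochsim
Title: Simulation and Optimization of Cochlear-Implant Electrode Insertion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A planar kinematic simulator for the insertion of preformed,
    self-curling cochlear-implant electrode arrays. Models the shape of the
    array as a function of stylet extraction (a logarithmic spiral plus up to
    three straight segments), builds its areal outline, generates 2D inner and
    outer cochlear lumen contours (from a triangulated surface mesh via a
    rotating cutting plane, or synthetically), and simulates step-by-step
    insertion under three strategies: manual Advance Off-Stylet with intuitive
    rotational compensation, rigid automated insertion through a drill canal,
    and an individually optimized insertion plan found by constrained search.
    Electrode-cochlea overlap at each step is scored geometrically and mapped
    to an ordinal trauma-risk grade (0-IV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    pracma,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
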