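Package: trusscage
Title: Strain Patterns on Trussed Titanium Interbody Cages in a Virtual Lumbar Spine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of mechanobiological strain patterns on the
    strut surface of a trussed (lattice) titanium interbody fusion cage after
    posterior lumbar interbody fusion. A lumped functional-spinal-unit chain
    reproduces follower-load and 20-degree extension/flexion protocols of the
    lumbar spine and hands segment-level boundary conditions to a 3D Timoshenko
    beam finite-element model of the cage strut lattice, coupled to the bony
    endplates through unilateral frictional foundation contact layers and a
    posterior pedicle-screw/rod parallel load path. Outputs include the fraction
    of strut surface strained beyond the bone-maintenance threshold (200
    microstrain), strain histograms, caudal contact pressures, peak von Mises
    stresses, intradiscal pressures, and cohort variability statistics for a
    seeded virtual patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
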