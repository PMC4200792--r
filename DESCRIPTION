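Package: loopfactor
Title: Monte Carlo and Elastic-Rod Models of Protein-Mediated DNA Looping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models short DNA loops anchored between the headpieces of the
    tetrameric Lac repressor at the level of rigid-body base-pair steps.
    Provides the frame algebra and elastic deformation energy of an ideal,
    inextensible, naturally straight B-DNA helix; Gaussian Monte Carlo
    sampling of chain configurations with half-chain pairwise combination
    and Jacobson-Stockmayer J-factor estimation; random decoration of loops
    with rigid, sharply bent HU protein footprints; parametric V-shaped
    repressor anchors in the four operator orientations; constrained
    minimization of the elastic energy of loops with fixed terminal
    base-pair frames; and loop-geometry analytics (bend and ribbon-twist
    profiles, writhe, linking number, Boltzmann populations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
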