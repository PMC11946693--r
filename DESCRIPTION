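Package: dioltraj
Title: Direct Conformational Analysis of Small Flexible Molecules in MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Direct determination of the conformational composition of small
    flexible molecules (1,3-propanediol and similar 1,3-diols) along molecular
    dynamics trajectories. Every target molecule in every recorded frame is
    assigned a symmetry-canonical four-letter torsion label (gauche/trans
    nomenclature), from which occupancy fractions, per-conformation and
    per-family lifetime statistics, and per-family intramolecular O...O
    distance tracks are computed. A hydroxyl-oxygen radial distribution
    function with multi-peak Lorentzian/Gaussian area decomposition is
    provided for contrast with the direct method. Includes readers for LAMMPS
    text dumps and (extended) XYZ trajectories, and a seeded Markov-chain
    synthetic trajectory generator with an internal-to-Cartesian builder so
    the whole pipeline is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
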