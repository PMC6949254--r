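Package: fretkin
Title: Kinetic Analysis of Single-Molecule FRET Trajectories with
    Degenerate-State Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse camera-based single-molecule
    FRET trajectories of reversible bimolecular interactions, developed
    around the EBS1*/IBS1* exon-intron tertiary contact of group II
    introns. Includes an exact-event continuous-time Markov chain trace
    simulator with camera binning and channel distortions, intensity
    corrections and FRET efficiency computation, molecule classification,
    threshold-based dwell-time extraction with per-molecule dissociation
    constants and multiexponential survival fits, a global hidden Markov
    model supporting degenerate FRET states with BIC model selection and
    likelihood-ratio error estimation, transition-state thermodynamics,
    and sugar pseudorotation analysis of nucleic-acid structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
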