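Package: sumdkin
Title: Supervised Sampling and Binding Kinetics for m6A Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for studying how the METTL3-METTL14
    methyltransferase senses N6-methyladenosine (m6A). Provides a supervised
    adaptive-sampling engine (windowed short trajectories accepted on a
    negative least-squares distance slope) over toy Langevin dynamics on
    funnel-shaped binding landscapes, together with forward models and
    nonlinear least-squares fitters for surface plasmon resonance
    sensorgrams (1:1 Langmuir and two-state reaction models with
    single-cycle injection schedules), fluorescence-polarization one-site
    binding isotherms, and Michaelis-Menten saturation curves. Ships the
    published SPR rate-constant tables for METTL3-METTL14 binding to GGACU
    RNA substrates and the equilibrium dissociation-constant algebra that
    reproduces them, plus trajectory analyses (center-of-mass distances,
    pocket residence, Kabsch superposition RMSD, per-frame energies) and
    synthetic-data generators for every input so the whole pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
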