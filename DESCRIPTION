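Package: etslaw
Title: Effective Time-Delay Rate Laws for Time-Varying Molecular Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the effective time-delay scheme (ETS), a generalization
    of the Michaelis-Menten and total quasi-steady-state (tQSSA) rate laws to
    molecular species whose total concentrations vary actively in time. Provides
    closed-form rate-law approximants (sQSSA, Michaelis-Menten, tQSSA, ETS, and
    their transcription-factor/DNA counterparts) together with exact mass-action
    reference simulators, a state-dependent delay-differential-equation engine,
    a positive-autoregulation circuit with bifurcation and induction-response
    analysis, a post-translational-modification cascade model of rhythmic
    circadian protein degradation, and least-squares kinetic parameter
    estimation benchmarks comparing delay-corrected and quasi-steady-state fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
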