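Package: ahmmtraj
Title: Weight-Trajectory Discovery in Aging Mouse Colonies via
    Autoregressive Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies latent body-weight trajectories in longitudinal,
    irregularly sampled rodent colony data using an autoregressive hidden
    Markov model with mixed Gaussian/categorical emissions (age, weight,
    sex, APOE genotype) and a sex-weight interaction. Provides EM fitting
    with random restarts, exact forward-backward and Viterbi inference,
    transition-matrix-based classification of ending states, trajectory
    grouping with mean curves and percent weight change from a midlife
    anchor, and a post-hoc validation battery (Kaplan-Meier curves,
    log-rank tests, composition chi-square tests, Welch t tests, adipose
    index, single-observation state inference for cross-sectional data).
    A synthetic-colony generator with known ground truth supports
    parameter-recovery and end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    readxl,
    withr
Config/testthat/edition: 3
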