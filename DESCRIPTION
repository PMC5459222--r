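Package: waitgo
Title: Reward-Rate-Optimal Decision Boundaries for Expanded-Judgment Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying time-varying decision boundaries in
    fixed-duration expanded-judgment tasks with Bernoulli cues. Solves the
    average-reward Markov decision process that yields reward-rate-optimal
    wait/go policies via belief updating and dynamic programming, evaluates
    the exact reward rate of arbitrary linear boundaries to map reward-rate
    landscapes, simulates synthetic cohorts of threshold and probabilistic
    agents on easy, difficult and mixed-difficulty games, and infers decision
    boundaries from trial records by wait/go logistic regression (line of
    indifference, circular slope differences, bootstrap confidence intervals,
    nondecision-time estimation) with BIC-based comparison of fixed versus
    time-varying boundary models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
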