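Package: tipmdp
Title: Policy Paradigms for Human-Environment Tipping Elements
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A stylized two-state, two-action Markov decision process of a
    human-environment tipping element, with closed-form policy values,
    classification of risky and cautious management policies under three
    governance paradigms (economic welfare optimization, sustainability,
    and the safe operating space), Monte Carlo and grid estimates of the
    parameter-space volume occupied by each paradigm combination, and
    case-study presets (climate, fisheries, farming) that convert residence
    timescales into transition probabilities and propagate parameter
    uncertainty into regime-membership probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
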