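Package: nutrichoice
Title: Economic Analysis of Nutrient-Guided Food Choices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how macronutrient content and nutrient-linked
    food textures shape economic food preferences in repeated binary choice
    tasks. Simulates choice sessions between nutrient-defined liquid rewards,
    estimates nutrient-value functions (psychometric indifference points and
    discrete-choice logistic models), quantifies individual differences via a
    preference dissimilarity index, tests texture mediation of fat preference
    with a bootstrapped path model, compares nutrient-valuation against
    energy-maximization accounts, computes Geometric Framework for Nutrition
    mixture-triangle balances against dietary reference points, and simulates
    nutrient-sensitive Rescorla-Wagner reinforcement learning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
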