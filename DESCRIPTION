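Package: cdforest
Title: Comparison Data and Comparison Data Forest Factor Retention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the number of factors to retain in exploratory
    factor analysis with simulation-based comparison data criteria. Provides
    the classical comparison data approach (sequential eigenvalue RMSR
    comparison with a Mann-Whitney U stopping rule), the comparison data
    forest (a random forest trained on features of comparison data sets
    generated under competing factor solutions), and the empirical Kaiser
    criterion, plus the iterative comparison-data population generator, a
    population factor-model simulator, and a Monte Carlo study harness for
    evaluating accuracy and bias of the criteria across crossed data
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    ranger,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
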