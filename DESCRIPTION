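Package: hdssmove
Title: Migration Typologies for Young People from HDSS Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying internal migration of children and
    adolescents in health and demographic surveillance system (HDSS)
    populations. Reduces residence-episode registers to a quarterly panel,
    detects residence changes between snapshots, classifies moves into a
    four-way typology (short/long crossed with independent/accompanied),
    derives rule-based household-composition categories and kin-proximity
    indicators from parent and spouse links, computes descriptive statistics
    with two-way cluster-robust variances, and fits multilevel multinomial
    logit models of move type with crossed random intercepts for individual
    and household. Includes a synthetic HDSS microsimulator (fertility,
    mortality, patrilocal marriage, divorce return-moves, child fostering,
    household relocation, external migration) so the full pipeline runs and
    is tested without access-restricted surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    sandwich,
    withr
Config/testthat/edition: 3
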