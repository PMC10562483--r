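Package: champ
Title: Conceptual Habitat Alteration Model for Ponding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how river barriers (dams, weirs, sluices, culverts,
    fords, ramps) alter upstream fish habitat through impoundment. Combines
    guild-level habitat-preference scores with barrier-type alteration scores
    into remaining-habitat proportions (RHp), weights them by expected guild
    composition of river macrohabitat types (wRHp), classifies survey sites
    into fish-community macrohabitat types via medoid clustering and a
    decision tree, derives reciprocal-rank expected guild proportions
    (target fish community), and extrapolates continental habitat alteration
    from a barrier inventory with corrections for missing barrier heights
    and inventory underreporting. Includes seeded synthetic-data generators
    so the full pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    cluster,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
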