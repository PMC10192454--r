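Package: kolacross
Title: Sexual Compatibility and Heterosis Analysis for Kola Crossing Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing controlled-pollination crossing trials in kola
    (Cola nitida), a sporophytically self-incompatible tree crop. Parses single
    and double hybrid cross pedigree labels, quantifies sexual compatibility from
    pod-set and pseudo-pod-set counts on a 0-5 class scale, contrasts cross types
    with binomial generalised linear models, summarises nut yield and quality
    traits with LSD or rank-based letter groupings, estimates mid-parent
    heterosis, heterobeltiosis and economic heterosis for single and double
    hybrids, and characterises crosses by principal components, Ward clustering
    and v-test category description. Includes a seeded simulator of sporophytic
    self-incompatibility crossing designs with additive-plus-dominance trait
    architecture, and packaged transcriptions of two published self-cross trait
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
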