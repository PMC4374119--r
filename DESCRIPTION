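Package: wikichem
Title: Structure Harvesting, Curation and Fingerprint-Screened Searching of
    Chemical Infobox Data
Version: 0.1.0
Authors@R:
    person("wikichem", "maintainers", email = "wikichem@example.org",
           role = c("aut", "cre"))
Description: Harvests SMILES strings from Chembox and Drugbox wiki-markup
    infoboxes, validates and kekulizes them with a classified error taxonomy
    (including the pyrrole-type nitrogen repair), canonicalizes structures for
    exact matching and duplicate detection, builds a JSON structure index
    carrying a 512-bit fragment-dictionary fingerprint per record, and answers
    exact, substructure (two-step fingerprint screen plus subgraph-isomorphism
    confirmation) and Tanimoto similarity queries with molecular-weight aware
    ranking. Includes Murcko scaffold frequency analysis, cross-reference
    disagreement classification, a deterministic synthetic corpus generator
    for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
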