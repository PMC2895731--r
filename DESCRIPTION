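Package: anatofun
Title: Pattern-Based Extraction of Anatomical Structure-Function Candidates
    from Phenotype Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining candidate anatomical-function assertions from
    OBO ontologies. Parses and writes the OBO Flatfile Format, normalizes
    category labels (lowercasing, rule-based English singularization),
    applies the functional-abnormality naming pattern to a phenotype,
    anatomy and biological-process ontology triple to extract
    structure-process pairs, evaluates the category-level
    has-function/realized-by relation semantics over finite instance
    models, emits the corresponding OWL2 property-chain axiom, and lints
    phenotype ontologies for the naming problems (plural mixing,
    disjunctive labels, "absent" used as a quality, permuted labels) that
    degrade such extraction. Includes deterministic synthetic-fixture
    generators with planted pattern instances and distractors so the whole
    pipeline is testable without downloading ontology releases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
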