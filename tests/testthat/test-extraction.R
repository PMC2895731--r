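worked <- make_worked_example_fixture()

test_that("keyword filter keeps abnormality terms, drops disease names", {
  kept <- filter_abnormality_terms(worked$phenotype)
  expect_true("HP:0000364" %in% kept)   # "abnormal" within "abnormality"
  expect_true("MP:0006325" %in% kept)   # "impaired hearing"
  expect_false("MP:0001967" %in% kept)  # "deafness", no qualifying synonym
  expect_identical(filter_abnormality_terms(obo_ontology()), character(0))
})

test_that("keyword filter also looks at synonyms and skips obsolete terms", {
  ont <- obo_ontology(list(
    obo_term("X:1", "hearing loss",
             synonyms = data.frame(text = "decreased hearing",
                                   scope = "EXACT")),
    obo_term("X:2", "abnormal gait", is_obsolete = TRUE)))
  expect_identical(filter_abnormality_terms(ont), "X:1")
})

test_that("process exclusion covers roots and optionally subtrees", {
  ont <- obo_ontology(list(
    obo_term("GO:0008150", "biological_process"),
    obo_term("GO:0001503", "ossification", parents = "GO:0008150"),
    obo_term("GO:X", "bone mineralization", parents = "GO:0001503")))
  cfg <- extraction_config()
  expect_warning(ids <- excluded_process_ids(ont, cfg), "not in ontology")
  expect_setequal(ids, c("GO:0001503", "GO:X"))
  cfg2 <- extraction_config(exclude_descendants = FALSE)
  expect_warning(ids2 <- excluded_process_ids(ont, cfg2), "not in ontology")
  expect_identical(ids2, "GO:0001503")
})

test_that("match_terms finds delimited hits after normalization", {
  owner <- worked$phenotype$terms[["HP:0000364"]]   # Hearing abnormality
  hits <- match_terms(owner, worked$process,
                      excluded = excluded_process_ids(worked$process))
  expect_identical(hits$id, "GO:0007605")
  expect_identical(hits$matched_text, "hearing")

  owner2 <- worked$phenotype$terms[["HP:0000598"]]  # Abnormality of the ears
  hits2 <- match_terms(owner2, worked$anatomy)
  expect_identical(hits2$id, "FMA:52780")           # Ear, after singularization

  # excluded targets are never returned
  hits3 <- match_terms(owner, worked$process,
                       excluded = names(worked$process$terms))
  expect_identical(nrow(hits3), 0L)
})

test_that("longest matched text wins within one target id", {
  owner <- obo_term("X:1", "abnormal sensory perception of sound")
  target <- obo_ontology(list(
    obo_term("GO:1", "sensory perception of sound",
             synonyms = data.frame(text = "sound", scope = "EXACT"))))
  hits <- match_terms(owner, target)
  expect_identical(hits$matched_text, "sensory perception of sound")
})

test_that("the worked example yields exactly the hearing pair", {
  pairs <- extract_pairs(worked$phenotype, worked$anatomy, worked$process)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$structure_id, "FMA:52780")
  expect_identical(pairs$process_id, "GO:0007605")
  ev <- attr(pairs, "evidence")
  expect_identical(ev$phenotype_id, "HP:0000364")
  expect_identical(ev$ancestor_id, "HP:0000598")
})

test_that("an empty phenotype ontology yields no pairs", {
  pairs <- extract_pairs(obo_ontology(), worked$anatomy, worked$process)
  expect_identical(nrow(pairs), 0L)
})

test_that("a table-style fixture recovers the blood/coagulation pair", {
  phenotype <- obo_ontology(list(
    obo_term("P:1", "abnormal blood"),
    obo_term("P:2", "abnormal blood coagulation", parents = "P:1")))
  anatomy <- obo_ontology(list(obo_term("A:1", "blood")))
  process <- obo_ontology(list(obo_term("G:1", "coagulation")))
  pairs <- suppressWarnings(extract_pairs(phenotype, anatomy, process))
  expect_true(any(pairs$structure_id == "A:1" & pairs$process_id == "G:1"))
})

test_that("extract_pairs equals the quadruple-enumeration oracle", {
  for (seed in 0:24) {
    fx <- make_random_fixture(seed, n_pairs = 3, n_distractors = 4)
    pairs <- suppressWarnings(
      extract_pairs(fx$phenotype, fx$anatomy, fx$process))
    expect_identical(
      pair_keys(pairs),
      oracle_extract_keys(fx$phenotype, fx$anatomy, fx$process),
      info = paste("seed", seed))
  }
})

test_that("every evidence C passes the filter and E is an ancestor of C", {
  for (seed in c(3, 11, 25)) {
    fx <- make_random_fixture(seed, n_pairs = 3, n_distractors = 4)
    pairs <- suppressWarnings(
      extract_pairs(fx$phenotype, fx$anatomy, fx$process))
    ev <- attr(pairs, "evidence")
    kept <- filter_abnormality_terms(fx$phenotype)
    for (i in seq_len(nrow(ev))) {
      expect_true(ev$phenotype_id[i] %in% kept)
      expect_true(ev$ancestor_id[i] %in%
                    ancestors(fx$phenotype, ev$phenotype_id[i]))
    }
  }
})

test_that("removing a keyword never adds a pair", {
  full <- extraction_config()
  reduced <- extraction_config(abnormality_keywords =
                                 c("abnormal", "impaired", "decreased"))
  for (seed in 0:4) {
    fx <- make_random_fixture(seed, n_pairs = 3, n_distractors = 4)
    k_full <- pair_keys(suppressWarnings(
      extract_pairs(fx$phenotype, fx$anatomy, fx$process, full)))
    k_red <- pair_keys(suppressWarnings(
      extract_pairs(fx$phenotype, fx$anatomy, fx$process, reduced)))
    expect_true(all(k_red %in% k_full))
  }
})

test_that("include_self_as_ancestor admits single-label patterns", {
  phenotype <- obo_ontology(list(
    obo_term("P:1", "abnormal pancreas insulin secretion")))
  anatomy <- obo_ontology(list(obo_term("A:1", "pancreas")))
  process <- obo_ontology(list(obo_term("G:1", "insulin secretion")))
  off <- suppressWarnings(extract_pairs(phenotype, anatomy, process))
  expect_identical(nrow(off), 0L)  # C has no proper ancestor
  on <- suppressWarnings(extract_pairs(
    phenotype, anatomy, process,
    extraction_config(include_self_as_ancestor = TRUE)))
  expect_identical(pair_keys(on), "A:1|G:1")
})

test_that("pairs TSV has the documented columns, one row per evidence", {
  pairs <- extract_pairs(worked$phenotype, worked$anatomy, worked$process)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(pairs, path)
  tab <- read.delim(path)
  expect_identical(names(tab),
                   c("structure_id", "structure_name", "process_id",
                     "process_name", "phenotype_id", "ancestor_id",
                     "matched_process_text", "matched_structure_text"))
  expect_identical(nrow(tab), nrow(attr(pairs, "evidence")))
})

test_that("config round-trips through YAML", {
  path <- withr::local_tempfile(lines = c(
    "abnormality_keywords: [abnormal, impaired]",
    "exclude_descendants: false"))
  cfg <- read_extraction_config(path)
  expect_identical(cfg$abnormality_keywords, c("abnormal", "impaired"))
  expect_false(cfg$exclude_descendants)
  expect_identical(cfg$excluded_process_roots,
                   c("GO:0032502", "GO:0043473", "GO:0001503"))
  bad <- withr::local_tempfile(lines = "not_a_field: 1")
  expect_error(read_extraction_config(bad), "unknown config field")
})
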