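two_ear_model <- function() {
  # two ear instances both bearing a hearing-function instance that is
  # realized by a sound-perception process instance
  instance_model(
    individuals = c("ear1", "ear2", "hf1", "sp1"),
    extensions = list(Ear = c("ear1", "ear2"), HearingF = "hf1",
                      HearingP = "sp1"),
    has_function = rbind(c("ear1", "hf1"), c("ear2", "hf1")),
    realized_by = rbind(c("hf1", "sp1")))
}

test_that("cc_has_function quantifies universally over the bearer category", {
  m <- two_ear_model()
  expect_true(cc_has_function(m, "Ear", "HearingF"))
  # one bearer without a function edge falsifies it
  m2 <- instance_model(
    individuals = c("ear1", "hf1"),
    extensions = list(Ear = "ear1", HearingF = "hf1"))
  expect_false(cc_has_function(m2, "Ear", "HearingF"))
  # empty bearer extension: vacuously true
  m3 <- instance_model("f1", extensions = list(E = character(), F = "f1"))
  expect_true(cc_has_function(m3, "E", "F"))
  expect_error(cc_has_function(m, "Nope", "HearingF"), "unknown category")
})

test_that("cc_realized_by tolerates unrealized functions", {
  m <- instance_model(
    individuals = c("f1", "p1", "q1"),
    extensions = list(F = "f1", P = "p1", Q = "q1"))
  # f1 has no realization: true for every process category
  expect_true(cc_realized_by(m, "F", "P"))
  expect_true(cc_realized_by(m, "F", "Q"))
  m2 <- instance_model(
    individuals = c("f1", "p1", "q1"),
    extensions = list(F = "f1", P = "p1", Q = "q1"),
    realized_by = rbind(c("f1", "p1")))
  expect_true(cc_realized_by(m2, "F", "P"))
  expect_false(cc_realized_by(m2, "F", "Q"))  # realization outside ext(Q)
})

test_that("the composite relation reports a witness and composes soundly", {
  m <- two_ear_model()
  res <- cc_has_function_realized_by(m, "Ear", "HearingP")
  expect_true(res)
  expect_identical(attr(res, "witness"), "HearingF")
  # no has_function edges from a non-empty bearer category: false
  m2 <- instance_model(
    individuals = c("x1", "f1", "p1"),
    extensions = list(E = "x1", F = "f1", P = "p1"))
  expect_false(cc_has_function_realized_by(m2, "E", "P"))
})

test_that("II composition is two-edge path existence", {
  m <- two_ear_model()
  expect_true(ii_has_function_realized_by(m, "ear1", "sp1"))
  expect_false(ii_has_function_realized_by(m, "sp1", "ear1"))
  expect_error(ii_has_function_realized_by(m, "nobody", "sp1"),
               "unknown individual")
  # brute-force edge join over random models
  set.seed(11)
  for (rep in 1:30) {
    ind <- c("x1", "x2", "f1", "f2", "p1", "p2")
    hf <- expand.grid(c("x1", "x2"), c("f1", "f2"),
                      stringsAsFactors = FALSE)
    rb <- expand.grid(c("f1", "f2"), c("p1", "p2"),
                      stringsAsFactors = FALSE)
    hf <- hf[runif(nrow(hf)) < 0.4, , drop = FALSE]
    rb <- rb[runif(nrow(rb)) < 0.4, , drop = FALSE]
    m <- instance_model(ind, list(),
                        has_function = if (nrow(hf)) hf else NULL,
                        realized_by = if (nrow(rb)) rb else NULL)
    for (x in c("x1", "x2")) for (p in c("p1", "p2")) {
      joined <- any(apply(expand.grid(seq_len(max(nrow(hf), 1)),
                                      seq_len(max(nrow(rb), 1))), 1,
                          function(ij) {
        nrow(hf) > 0 && nrow(rb) > 0 &&
          hf[ij[1], 1] == x && hf[ij[1], 2] == rb[ij[2], 1] &&
          rb[ij[2], 2] == p
      }))
      expect_identical(ii_has_function_realized_by(m, x, p), joined)
    }
  }
})

test_that("composite CC relation matches direct quantifier evaluation on an exhaustive model family", {
  models <- enumerate_models(bearers = c("x1", "x2"), funs = c("f1", "f2"),
                             procs = "p1", n_fcat = 2L)
  expect_gt(length(models), 8000)
  cands <- c("F1", "F2")
  disagreements <- 0L
  composition_violations <- 0L
  vacuity_violations <- 0L
  for (m in models) {
    got <- isTRUE(cc_has_function_realized_by(m, "E", "P",
                                              candidates = cands))
    if (got != oracle_cc_hfrb(m, "E", "P", cands))
      disagreements <- disagreements + 1L
    for (f in cands) {
      if (cc_has_function(m, "E", f) && cc_realized_by(m, f, "P") && !got)
        composition_violations <- composition_violations + 1L
    }
    if (!length(m$extensions$E) &&
        !all(vapply(cands, function(f) cc_has_function(m, "E", f),
                    logical(1))))
      vacuity_violations <- vacuity_violations + 1L
  }
  expect_identical(disagreements, 0L)
  expect_identical(composition_violations, 0L)
  expect_identical(vacuity_violations, 0L)
})

test_that("CC can hold while II fails everywhere: unrealized functions", {
  # every ear bears a hearing function, realizations (none exist) would be
  # HearingP processes — yet no individual pair is II-related
  m <- instance_model(
    individuals = c("ear1", "hf1", "sp1"),
    extensions = list(Ear = "ear1", HearingF = "hf1", HearingP = "sp1"),
    has_function = rbind(c("ear1", "hf1")),
    realized_by = NULL)
  expect_true(cc_has_function_realized_by(m, "Ear", "HearingP"))
  for (x in m$extensions$Ear) for (p in m$extensions$HearingP)
    expect_false(ii_has_function_realized_by(m, x, p))
})

test_that("the property-chain axiom is deterministic and reparses", {
  a1 <- emit_property_chain_axiom()
  a2 <- emit_property_chain_axiom()
  expect_identical(a1, a2)
  expect_match(a1, "has_function", fixed = TRUE)
  expect_match(a1, "realized_by", fixed = TRUE)
  expect_match(a1, "has_function_realized_by", fixed = TRUE)
  expect_match(a1, "SubObjectPropertyOf(ObjectPropertyChain(", fixed = TRUE)
  # the OBO half reparses into a typedef with one chain of length 2
  obo_part <- sub(".*?\\[Typedef\\]", "[Typedef]", a1)
  ont <- parse_obo(obo_part)
  expect_length(ont$typedefs, 1L)
  expect_length(ont$typedefs[[1L]]$holds_over_chain, 1L)
  expect_length(ont$typedefs[[1L]]$holds_over_chain[[1L]], 2L)
  expect_error(emit_property_chain_axiom(chain = "bad name"),
               "identifier fragments")
})

test_that("instance models load from YAML", {
  path <- withr::local_tempfile(lines = c(
    "individuals: [ear1, hf1, sp1]",
    "extensions:",
    "  Ear: [ear1]",
    "  HearingF: [hf1]",
    "  HearingP: [sp1]",
    "has_function:",
    "  - [ear1, hf1]",
    "realized_by:",
    "  - [hf1, sp1]"))
  m <- read_instance_model(path)
  expect_true(cc_has_function_realized_by(m, "Ear", "HearingP"))
  expect_true(ii_has_function_realized_by(m, "ear1", "sp1"))
})
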