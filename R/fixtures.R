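# Deterministic fixture ontologies: the worked hearing example assembled
# from in-ontology terms, and randomized planted-pattern triples with
# distractors, so the extraction pipeline is testable without downloading
# any ontology release. All identifiers here are synthetic stand-ins for
# the real HPO/MPO/GO/FMA entries they name.

#' Worked-example fixture triple
#'
#' Builds the miniature phenotype/anatomy/process ontology triple around the
#' hearing example: "Hearing abnormality" (HP:0000364) is_a "Abnormality of
#' the ears" (HP:0000598); the process ontology holds "sensory perception of
#' sound" (GO:0007605) with its exact synonym "hearing" plus the three
#' excluded polysemous roots; the anatomy ontology holds "Ear" (FMA:52780).
#' The phenotype ontology additionally carries the naming-problem terms the
#' lint rules target: the disjunctive "abnormality of tear glands OR tear
#' production" (HP:0000251), the singular/plural pair "abnormal ear lobe" /
#' "absent ear lobes" (MP:0003677/MP:0003678), and the permuted-label family
#' around hearing (MP:0001963, MP:0001965 with synonyms "hearing
#' disability" and "hearing impairment", MP:0001967 "deafness",
#' MP:0006325 "impaired hearing"). Generation is deterministic.
#'
#' @return List with components `phenotype`, `anatomy`, `process`, each an
#'   [obo_ontology].
#' @examples
#' fx <- make_worked_example_fixture()
#' extract_pairs(fx$phenotype, fx$anatomy, fx$process)
#' @export
make_worked_example_fixture <- function() {
  syn <- function(texts, scope = "EXACT")
    data.frame(text = texts, scope = scope, stringsAsFactors = FALSE)
  phenotype <- obo_ontology(list(
    obo_term("HP:0000118", "Phenotypic abnormality"),
    obo_term("HP:0000598", "Abnormality of the ears",
             parents = "HP:0000118"),
    obo_term("HP:0000364", "Hearing abnormality", parents = "HP:0000598"),
    obo_term("HP:0000251", "Abnormality of tear glands OR tear production",
             parents = "HP:0000118"),
    obo_term("MP:0000001", "mammalian phenotype"),
    obo_term("MP:0003677", "abnormal ear lobe", parents = "MP:0000001"),
    obo_term("MP:0003678", "absent ear lobes", parents = "MP:0003677"),
    obo_term("MP:0001963", "abnormal hearing physiology",
             parents = "MP:0000001"),
    obo_term("MP:0001965", "abnormal hearing",
             synonyms = syn(c("hearing disability", "hearing impairment")),
             parents = "MP:0001963"),
    obo_term("MP:0001967", "deafness",
             definition = paste("A sensory perception of sound process",
                                "bearing the quality PATO:0000462 (absent)."),
             parents = "MP:0001963"),
    obo_term("MP:0006325", "impaired hearing", parents = "MP:0001963")),
    header = list(`format-version` = "1.2"))
  process <- obo_ontology(list(
    obo_term("GO:0008150", "biological_process"),
    obo_term("GO:0007605", "sensory perception of sound",
             synonyms = syn("hearing"), parents = "GO:0008150"),
    obo_term("GO:0050910",
             paste("detection of mechanical stimulus involved in sensory",
                   "perception of sound"),
             parents = "GO:0008150",
             relationships = data.frame(relation = "part_of",
                                        target = "GO:0007605",
                                        stringsAsFactors = FALSE)),
    obo_term("GO:0032502", "developmental process", parents = "GO:0008150"),
    obo_term("GO:0043473", "pigmentation", parents = "GO:0008150"),
    obo_term("GO:0001503", "ossification", parents = "GO:0008150")),
    header = list(`format-version` = "1.2"))
  anatomy <- obo_ontology(list(
    obo_term("FMA:62955", "Anatomical structure"),
    obo_term("FMA:52780", "Ear", parents = "FMA:62955")),
    header = list(`format-version` = "1.2"))
  list(phenotype = phenotype, anatomy = anatomy, process = process)
}

# run expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

structure_word_pool <- c(
  "pancreas", "uterus", "heart", "liver", "kidney", "lung", "spleen",
  "brain", "stomach", "bladder", "thymus", "retina")
process_word_pool <- c(
  "coagulation", "lactation", "angiogenesis", "fertilization", "diestrus",
  "secretion", "apoptosis", "respiration", "digestion", "circulation",
  "filtration", "excretion")

# pronounceable nonsense tokens; final consonant excludes s so that
# pluralization/singularization is exactly +s/-s
make_nonsense <- function(n, taboo) {
  cons <- c("b", "d", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    w <- paste0(sample(cons, 1), sample(vow, 1), sample(cons, 1),
                sample(vow, 1), sample(cons, 1))
    if (!w %in% c(taboo, out)) out <- c(out, w)
  }
  out
}

pluralize_token <- function(w) {
  rules <- default_rules()
  if (w %in% rules$invariant) return(w)
  n <- nchar(w)
  if (substr(w, n - 1L, n) %in% c("us", "is", "ss")) return(w)
  if (grepl("[^aeiou]y$", w)) return(paste0(substr(w, 1L, n - 1L), "ies"))
  if (grepl("(s|x|z|ch|sh)$", w)) return(paste0(w, "es"))
  paste0(w, "s")
}

distractor_kinds <- c("no_keyword", "concatenated", "excluded_process",
                      "anatomy_not_ancestor")

#' Randomized planted-pattern fixture triple
#'
#' Generates a phenotype/anatomy/process ontology triple with `n_pairs`
#' planted pattern instances and `n_distractors` near-misses, fully
#' reproducible from `seed`. Each planted pair contributes a phenotype term
#' C named `"<keyword> <structure> <process>"` (keyword drawn from the
#' abnormality set, structure word randomly inflected) placed is_a under an
#' ancestor E named `"abnormality of the <structure plural>"`, an anatomy
#' term for the structure word and a process term for the process word.
#' Distractor kinds are cycled, one per distractor, each falsifying exactly
#' one pattern condition: a keyword-free phenotype term; a process name
#' concatenated to the structure word without a token boundary; a process
#' placed under an excluded polysemy root; and an anatomy word occurring
#' only in a term that is not an ancestor of the pattern term. Structure and
#' process words mix real anatomical/physiological vocabulary with
#' pronounceable nonsense tokens and are used at most once each, so no
#' accidental cross-matches arise.
#'
#' @param seed Integer seed.
#' @param n_pairs Number of planted pairs (>= 0).
#' @param n_distractors Number of distractor constructions (>= 0).
#' @return List with `phenotype`, `anatomy`, `process` ([obo_ontology]
#'   objects) and `truth`, a list holding `pairs` (data frame
#'   `structure_id`, `process_id`), `distractor_counts` (named integer
#'   vector by kind) and `seed`.
#' @examples
#' fx <- make_random_fixture(seed = 1, n_pairs = 2, n_distractors = 4)
#' fx$truth$pairs
#' @export
make_random_fixture <- function(seed, n_pairs = 3, n_distractors = 4) {
  stopifnot(n_pairs >= 0, n_distractors >= 0)
  with_seed(seed, {
    n_words <- n_pairs + n_distractors
    taboo <- c(structure_word_pool, process_word_pool,
               "abnormal", "impaired", "decreased", "increased", "finding")
    s_pool <- sample(structure_word_pool)
    p_pool <- sample(process_word_pool)
    if (n_words > length(s_pool)) {
      need <- n_words - length(s_pool)
      extra <- make_nonsense(2L * need, taboo)
      s_pool <- c(s_pool, extra[seq_len(need)])
      p_pool <- c(p_pool, extra[need + seq_len(need)])
    }
    s_words <- s_pool[seq_len(n_words)]
    p_words <- p_pool[seq_len(n_words)]
    nonsense_ctx <- make_nonsense(max(n_distractors, 1L),
                                  c(taboo, s_pool, p_pool))

    keywords <- c("abnormal", "impaired", "decreased", "increased")
    ph <- list(obo_term("PH:0000001", "organism phenotype"))
    an <- list(obo_term("AN:0000001", "body structure"))
    pr <- list(obo_term("GO:0008150", "biological_process"),
               obo_term("GO:0032502", "developmental process",
                        parents = "GO:0008150"),
               obo_term("GO:0043473", "pigmentation", parents = "GO:0008150"),
               obo_term("GO:0001503", "ossification", parents = "GO:0008150"))
    an_id <- function(i) sprintf("AN:%07d", 1000000 + i)
    pr_id <- function(i) sprintf("GO:%07d", 9000000 + i)

    truth_pairs <- data.frame(structure_id = character(),
                              process_id = character(),
                              stringsAsFactors = FALSE)
    add_anatomy <- function(i)
      an[[length(an) + 1L]] <<- obo_term(an_id(i), s_words[i],
                                         parents = "AN:0000001")
    add_process <- function(i, parent = "GO:0008150")
      pr[[length(pr) + 1L]] <<- obo_term(pr_id(i), p_words[i],
                                         parents = parent)
    add_e <- function(id, i)
      ph[[length(ph) + 1L]] <<- obo_term(
        id, paste("abnormality of the", pluralize_token(s_words[i])),
        parents = "PH:0000001")

    idx <- 0L
    for (k in seq_len(n_pairs)) {
      idx <- idx + 1L
      i <- idx
      add_anatomy(i)
      add_process(i)
      e_id <- sprintf("PH:%07d", 1000000 + i)
      add_e(e_id, i)
      s_form <- if (stats::runif(1) < 0.5) s_words[i]
                else pluralize_token(s_words[i])
      ph[[length(ph) + 1L]] <- obo_term(
        sprintf("PH:%07d", 2000000 + i),
        paste(sample(keywords, 1), s_form, p_words[i]),
        parents = e_id)
      truth_pairs <- rbind(truth_pairs,
                           data.frame(structure_id = an_id(i),
                                      process_id = pr_id(i),
                                      stringsAsFactors = FALSE))
    }

    kinds_used <- character(0)
    for (k in seq_len(n_distractors)) {
      idx <- idx + 1L
      i <- idx
      kind <- distractor_kinds[((k - 1L) %% 4L) + 1L]
      kinds_used <- c(kinds_used, kind)
      e_id <- sprintf("PH:%07d", 1000000 + i)
      c_id <- sprintf("PH:%07d", 2000000 + i)
      if (kind == "no_keyword") {
        add_anatomy(i); add_process(i); add_e(e_id, i)
        ph[[length(ph) + 1L]] <- obo_term(
          c_id, paste(s_words[i], p_words[i], "finding"), parents = e_id)
      } else if (kind == "concatenated") {
        add_anatomy(i); add_process(i); add_e(e_id, i)
        ph[[length(ph) + 1L]] <- obo_term(
          c_id, paste(sample(keywords, 1),
                      paste0(s_words[i], p_words[i])),
          parents = e_id)
      } else if (kind == "excluded_process") {
        add_anatomy(i)
        add_process(i, parent = sample(c("GO:0032502", "GO:0043473",
                                         "GO:0001503"), 1))
        add_e(e_id, i)
        ph[[length(ph) + 1L]] <- obo_term(
          c_id, paste(sample(keywords, 1), s_words[i], p_words[i]),
          parents = e_id)
      } else {  # anatomy_not_ancestor
        add_anatomy(i)
        add_process(i)
        add_e(sprintf("PH:%07d", 4000000 + i), i)  # NOT an ancestor of C
        ph[[length(ph) + 1L]] <- obo_term(
          e_id, paste("finding of", nonsense_ctx[k]),
          parents = "PH:0000001")
        ph[[length(ph) + 1L]] <- obo_term(
          c_id, paste(sample(keywords, 1), p_words[i]), parents = e_id)
      }
    }

    hdr <- list(`format-version` = "1.2")
    list(phenotype = obo_ontology(ph, header = hdr),
         anatomy = obo_ontology(an, header = hdr),
         process = obo_ontology(pr, header = hdr),
         truth = list(pairs = truth_pairs,
                      distractor_counts = if (length(kinds_used))
                        table(kinds_used) else table(character()),
                      seed = seed))
  })
}

#' Write a fixture triple to disk
#'
#' Serializes the three ontologies of a fixture as `phenotype.obo`,
#' `anatomy.obo` and `process.obo` in `dir`, plus `truth.tsv` with the
#' planted pairs when present.
#'
#' @param fixture A list from [make_worked_example_fixture()] or
#'   [make_random_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  serialize_obo(fixture$phenotype, file.path(dir, "phenotype.obo"))
  serialize_obo(fixture$anatomy, file.path(dir, "anatomy.obo"))
  serialize_obo(fixture$process, file.path(dir, "process.obo"))
  if (!is.null(fixture$truth))
    utils::write.table(fixture$truth$pairs, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
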