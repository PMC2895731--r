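# Naming-problem lint for phenotype ontologies. Each rule targets a label
# pathology that degrades pattern-based extraction:
#   R1 plural_mix       — a term and an is_a ancestor/descendant share a word
#                         used in singular form in one label and plural in
#                         the other ("abnormal ear lobe" / "absent ear lobes")
#   R2 or_label         — a disjunctive label mixing structural and
#                         functional abnormalities ("... tear glands OR tear
#                         production")
#   R3 absent_quality   — "absent" used as if it were a quality, either
#                         leading a label or via a PATO:0000462 reference
#   R4 label_permutation— two terms whose labels are word-permutation
#                         variants of each other ("impaired hearing" /
#                         "hearing impairment")
# All findings are warnings: these are curation suggestions, not errors.

lint_rule_ids <- c("R1", "R2", "R3", "R4")

# raw word tokens of a label: lowercased, hyphens split, edge punctuation
# stripped, but NOT singularized (R1 needs the raw plurality)
raw_tokens <- function(label) {
  txt <- gsub("-", " ", tolower(label), fixed = TRUE)
  tok <- strsplit(txt, "\\s+")[[1L]]
  tok <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tok)
  tok[nzchar(tok)]
}

# Light derivational stem used only by R4 on top of singularization, so that
# "impaired"/"impairment" and "hearing"/"hears" collapse to one stem.
derivational_stem <- function(token) {
  w <- singularize(token)
  for (suf in c("ation", "ment", "ness", "ance", "ence", "ity", "ing",
                "ed")) {
    if (endsWith(w, suf) && nchar(w) - nchar(suf) >= 3L) {
      w <- substr(w, 1L, nchar(w) - nchar(suf))
      break
    }
  }
  w
}

new_finding <- function(rule, term_ids, message) {
  data.frame(rule = rule, term_ids = paste(term_ids, collapse = ","),
             message = message, severity = "warning",
             stringsAsFactors = FALSE)
}

lint_r1 <- function(ontology) {
  findings <- list()
  ids <- names(ontology$terms)
  toks <- lapply(ontology$terms, function(t) unique(raw_tokens(t$name)))
  sing <- lapply(toks, singularize)
  for (cid in ids) {
    anc <- suppressWarnings(ancestors(ontology, cid))
    for (aid in anc) {
      # each unordered pair once: child side reports
      a <- toks[[cid]]; sa <- sing[[cid]]
      b <- toks[[aid]]; sb <- sing[[aid]]
      for (i in seq_along(a)) {
        j <- which(sb == sa[i] & b != a[i])
        if (length(j)) {
          findings[[length(findings) + 1L]] <- new_finding(
            "R1", sort(c(cid, aid)),
            sprintf("singular/plural mix across is_a: \"%s\" (%s) vs \"%s\" (%s)",
                    a[i], cid, b[j[1L]], aid))
          break
        }
      }
    }
  }
  findings
}

lint_r2 <- function(ontology) {
  findings <- list()
  for (t in ontology$terms) {
    for (lab in c(t$name, t$synonyms$text)) {
      if ("or" %in% raw_tokens(lab)) {
        findings[[length(findings) + 1L]] <- new_finding(
          "R2", t$id,
          sprintf("disjunctive label mixing abnormality kinds: \"%s\"", lab))
        break
      }
    }
  }
  findings
}

lint_r3 <- function(ontology) {
  findings <- list()
  for (t in ontology$terms) {
    lead <- vapply(c(t$name, t$synonyms$text), function(lab) {
      tok <- raw_tokens(lab)
      length(tok) > 0L && tok[1L] == "absent"
    }, logical(1))
    pato <- grepl("PATO:0000462", c(t$definition, t$extras), fixed = TRUE)
    if (any(lead) || any(pato)) {
      findings[[length(findings) + 1L]] <- new_finding(
        "R3", t$id,
        sprintf("\"absent\" used as a quality in \"%s\"", t$name))
    }
  }
  findings
}

lint_r4 <- function(ontology) {
  findings <- list()
  labels <- list()   # key (sorted stem multiset) -> data.frame(id, label)
  for (t in ontology$terms) {
    for (lab in unique(c(t$name, t$synonyms$text))) {
      stems <- vapply(raw_tokens(lab), derivational_stem, character(1))
      if (!length(stems)) next
      key <- paste(sort(stems), collapse = "\r")
      labels[[key]] <- rbind(labels[[key]],
                             data.frame(id = t$id, label = lab,
                                        stringsAsFactors = FALSE))
    }
  }
  for (key in sort(names(labels))) {
    grp <- unique(labels[[key]])
    if (length(unique(grp$id)) < 2L) next
    # only flag when the surface labels actually differ
    if (length(unique(grp$label)) < 2L) next
    findings[[length(findings) + 1L]] <- new_finding(
      "R4", sort(unique(grp$id)),
      sprintf("permuted label variants: %s",
              paste(sprintf("\"%s\" (%s)", grp$label, grp$id),
                    collapse = ", ")))
  }
  findings
}

#' Lint an ontology for naming problems
#'
#' Applies the enabled rules (see the rule catalogue above) and returns one
#' finding per violation, sorted by (rule, first term id). Lint is
#' read-only and deterministic.
#'
#' @param ontology An [obo_ontology].
#' @param rules Subset of `c("R1","R2","R3","R4")`; unknown ids are a
#'   configuration error.
#' @return A data frame of class `lint_findings` with columns `rule`,
#'   `term_ids` (comma-joined), `message`, `severity`.
#' @examples
#' fx <- make_worked_example_fixture()
#' run_lint(fx$phenotype)
#' @export
run_lint <- function(ontology, rules = lint_rule_ids) {
  stopifnot(inherits(ontology, "obo_ontology"))
  unknown <- setdiff(rules, lint_rule_ids)
  if (length(unknown))
    stop("unknown lint rule id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  findings <- list()
  if ("R1" %in% rules) findings <- c(findings, lint_r1(ontology))
  if ("R2" %in% rules) findings <- c(findings, lint_r2(ontology))
  if ("R3" %in% rules) findings <- c(findings, lint_r3(ontology))
  if ("R4" %in% rules) findings <- c(findings, lint_r4(ontology))
  out <- if (length(findings)) unique(do.call(rbind, findings))
  else data.frame(rule = character(), term_ids = character(),
                  message = character(), severity = character(),
                  stringsAsFactors = FALSE)
  out <- out[order(out$rule, out$term_ids), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lint_findings", "data.frame")
  out
}

#' Write lint findings as TSV
#'
#' @param findings A `lint_findings` data frame from [run_lint()].
#' @param path Output file path or connection.
#' @return `findings`, invisibly.
#' @export
write_lint_tsv <- function(findings, path) {
  utils::write.table(findings[, c("rule", "term_ids", "message")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(findings)
}
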