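# The four-condition naming pattern over a (phenotype, anatomy, process)
# ontology triple:
#   1. a phenotype category C with a name/synonyms,
#   2. a process category D whose name or synonym occurs whitespace-delimited
#      in a label of C,
#   3. an is_a ancestor E of C,
#   4. an anatomy category F whose name or synonym occurs whitespace-delimited
#      in a label of E.
# Each such quadruple contributes the candidate structure-process pair (F, D),
# read as: the structure F has some function realized by processes of kind D.

#' Extraction configuration
#'
#' Collects the tunable parameters of the pattern extraction.
#'
#' @param abnormality_keywords Lowercase keywords; a phenotype term takes part
#'   only when its name or a synonym contains one of them as a character
#'   substring (so "abnormal" also admits "abnormality"). The default set
#'   targets abnormality descriptions and excludes disease-named categories
#'   such as "Deafness".
#' @param excluded_process_roots Process term ids removed from matching.
#'   The defaults drop developmental process (GO:0032502), pigmentation
#'   (GO:0043473) and ossification (GO:0001503), whose labels are polysemous
#'   between a process and the state it results in.
#' @param exclude_descendants Exclude the whole is_a subtree under each
#'   excluded root (default), or only the listed roots themselves.
#' @param synonym_scopes_used Synonym scope tags that participate in
#'   matching; default all four.
#' @param include_self_as_ancestor Allow `E = C`, i.e. match the anatomy
#'   against the pattern term's own label (for single-label cases like
#'   "abnormal pancreas insulin secretion"). Default `FALSE`: the pattern
#'   reads the structure off a proper ancestor.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(
    abnormality_keywords = c("abnormal", "impaired", "decreased", "increased"),
    excluded_process_roots = c("GO:0032502", "GO:0043473", "GO:0001503"),
    exclude_descendants = TRUE,
    synonym_scopes_used = c("EXACT", "BROAD", "NARROW", "RELATED"),
    include_self_as_ancestor = FALSE) {
  if (!length(abnormality_keywords))
    stop("abnormality_keywords must be non-empty", call. = FALSE)
  if (any(abnormality_keywords != tolower(abnormality_keywords)))
    stop("abnormality_keywords must be lowercase", call. = FALSE)
  structure(list(abnormality_keywords = abnormality_keywords,
                 excluded_process_roots = excluded_process_roots,
                 exclude_descendants = isTRUE(exclude_descendants),
                 synonym_scopes_used = synonym_scopes_used,
                 include_self_as_ancestor = isTRUE(include_self_as_ancestor)),
            class = "extraction_config")
}

#' Read an extraction configuration from a YAML file
#'
#' The file may set any subset of the [extraction_config()] fields; unset
#' fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `extraction_config`.
#' @export
read_extraction_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(extraction_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(extraction_config, vals)
}

# All labels of a term that take part in matching: the name plus synonyms
# whose scope is enabled.
term_labels <- function(term, config) {
  syn <- term$synonyms
  texts <- syn$text[syn$scope %in% config$synonym_scopes_used]
  out <- c(if (nzchar(term$name)) term$name, texts)
  unique(out)
}

#' Phenotype terms admitted by the abnormality-keyword filter
#'
#' Keeps the non-obsolete terms whose lowercased name or any lowercased
#' synonym contains at least one configured keyword as a character
#' substring. This excludes categories named after diseases ("Deafness")
#' while keeping e.g. "Hearing abnormality" ("abnormal" is a substring of
#' "abnormality").
#'
#' @param phenotype An [obo_ontology].
#' @param config An [extraction_config()].
#' @return Character vector of term ids, sorted.
#' @export
filter_abnormality_terms <- function(phenotype,
                                     config = extraction_config()) {
  stopifnot(inherits(phenotype, "obo_ontology"))
  keep <- vapply(phenotype$terms, function(t) {
    if (t$is_obsolete) return(FALSE)
    labels <- tolower(c(t$name, t$synonyms$text))
    any(vapply(config$abnormality_keywords,
               function(k) any(grepl(k, labels, fixed = TRUE)),
               logical(1)))
  }, logical(1))
  sort(names(phenotype$terms)[keep])
}

#' Process terms excluded from matching
#'
#' The configured excluded roots present in the ontology plus, when
#' `exclude_descendants` is set, their whole is_a subtrees. Roots absent
#' from the ontology are ignored with a warning.
#'
#' @param process An [obo_ontology].
#' @param config An [extraction_config()].
#' @return Character vector of term ids, sorted.
#' @export
excluded_process_ids <- function(process, config = extraction_config()) {
  stopifnot(inherits(process, "obo_ontology"))
  roots <- config$excluded_process_roots
  missing <- setdiff(roots, names(process$terms))
  if (length(missing))
    warning("excluded process root(s) not in ontology: ",
            paste(missing, collapse = ", "), call. = FALSE)
  roots <- intersect(roots, names(process$terms))
  out <- roots
  if (config$exclude_descendants)
    for (r in roots) out <- union(out, descendants(process, r))
  sort(out)
}

#' Match one term's labels against a target ontology
#'
#' For every non-obsolete, non-excluded target term, tests each of the
#' target's labels (name and in-scope synonyms) for whitespace-delimited
#' containment in each of `label_owner`'s labels, on normalized token lists.
#' Hits are deduplicated per target id, keeping the longest matched target
#' text (most tokens, then most characters).
#'
#' @param label_owner An [obo_term] whose labels act as the haystack.
#' @param target An [obo_ontology] whose term labels act as needles.
#' @param excluded Character vector of target ids never returned.
#' @param config An [extraction_config()].
#' @return Data frame with columns `id` and `matched_text`, ordered by `id`.
#' @export
match_terms <- function(label_owner, target, excluded = character(),
                        config = extraction_config()) {
  stopifnot(inherits(label_owner, "obo_term"),
            inherits(target, "obo_ontology"))
  owner_norm <- lapply(term_labels(label_owner, config), normalize_label)
  owner_norm <- owner_norm[vapply(owner_norm,
                                  function(x) length(x$tokens) > 0L,
                                  logical(1))]
  hits_id <- character(0)
  hits_text <- character(0)
  for (t in target$terms) {
    if (t$is_obsolete || t$id %in% excluded) next
    best <- NULL
    for (lab in term_labels(t, config)) {
      nl <- normalize_label(lab)
      if (!length(nl$tokens)) next
      if (any(vapply(owner_norm, contains_delimited, logical(1),
                     needle = nl))) {
        if (is.null(best) ||
            length(nl$tokens) > length(best$tokens) ||
            (length(nl$tokens) == length(best$tokens) &&
             nchar(lab) > nchar(best$source)))
          best <- nl
      }
    }
    if (!is.null(best)) {
      hits_id <- c(hits_id, t$id)
      hits_text <- c(hits_text, best$source)
    }
  }
  ord <- order(hits_id)
  data.frame(id = hits_id[ord], matched_text = hits_text[ord],
             stringsAsFactors = FALSE)
}

#' Extract structure-process pairs from an ontology triple
#'
#' Applies the four-condition naming pattern: for every phenotype term C
#' passing the abnormality-keyword filter whose labels contain a process
#' term D's label whitespace-delimited, and every is_a ancestor E of C whose
#' labels contain an anatomy term F's label, the candidate pair (F, D) is
#' emitted — the anatomical structure F has some function realized by
#' processes of kind D. Pairs are unique on (structure, process) with
#' evidence quadruples merged, and ordered by (structure id, process id).
#'
#' @param phenotype,anatomy,process Parsed [obo_ontology] objects.
#' @param config An [extraction_config()].
#' @param verbose Log per-stage counts to standard error.
#' @return An object of class `structure_process_pairs`: a data frame with
#'   columns `structure_id`, `structure_name`, `process_id`, `process_name`
#'   (one row per pair) and an `evidence` attribute — a data frame with one
#'   row per supporting quadruple (`structure_id`, `process_id`,
#'   `phenotype_id`, `ancestor_id`, `matched_process_text`,
#'   `matched_structure_text`).
#' @examples
#' fx <- make_worked_example_fixture()
#' extract_pairs(fx$phenotype, fx$anatomy, fx$process)
#' @export
extract_pairs <- function(phenotype, anatomy, process,
                          config = extraction_config(), verbose = FALSE) {
  stopifnot(inherits(phenotype, "obo_ontology"),
            inherits(anatomy, "obo_ontology"),
            inherits(process, "obo_ontology"))
  log_stage <- function(...) if (verbose) message(sprintf(...))

  candidates <- filter_abnormality_terms(phenotype, config)
  excluded <- excluded_process_ids(process, config)
  log_stage("phenotype terms: %d (%d after keyword filter)",
            length(phenotype$terms), length(candidates))
  log_stage("process terms: %d (%d excluded)",
            length(process$terms), length(excluded))

  # anatomy matches per ancestor are cached: many C share ancestors
  anat_cache <- new.env(parent = emptyenv())
  anatomy_hits <- function(eid) {
    if (!is.null(anat_cache[[eid]])) return(anat_cache[[eid]])
    hits <- match_terms(phenotype$terms[[eid]], anatomy,
                        excluded = character(), config = config)
    anat_cache[[eid]] <- hits
    hits
  }

  ev <- list()
  n_process_matches <- 0L
  for (cid in candidates) {
    d_hits <- match_terms(phenotype$terms[[cid]], process,
                          excluded = excluded, config = config)
    if (!nrow(d_hits)) next
    n_process_matches <- n_process_matches + nrow(d_hits)
    anc <- suppressWarnings(
      ancestors(phenotype, cid,
                include_self = config$include_self_as_ancestor))
    for (eid in anc) {
      f_hits <- anatomy_hits(eid)
      if (!nrow(f_hits)) next
      for (di in seq_len(nrow(d_hits))) for (fi in seq_len(nrow(f_hits))) {
        ev[[length(ev) + 1L]] <- data.frame(
          structure_id = f_hits$id[fi],
          process_id = d_hits$id[di],
          phenotype_id = cid,
          ancestor_id = eid,
          matched_process_text = d_hits$matched_text[di],
          matched_structure_text = f_hits$matched_text[fi],
          stringsAsFactors = FALSE)
      }
    }
  }
  log_stage("phenotype terms with process matches: %d", n_process_matches)

  evidence <- if (length(ev)) do.call(rbind, ev)
  else data.frame(structure_id = character(), process_id = character(),
                  phenotype_id = character(), ancestor_id = character(),
                  matched_process_text = character(),
                  matched_structure_text = character(),
                  stringsAsFactors = FALSE)
  evidence <- unique(evidence)
  evidence <- evidence[order(evidence$structure_id, evidence$process_id,
                             evidence$phenotype_id, evidence$ancestor_id), ,
                       drop = FALSE]
  rownames(evidence) <- NULL

  key <- unique(evidence[, c("structure_id", "process_id")])
  rownames(key) <- NULL
  pairs <- data.frame(
    structure_id = key$structure_id,
    structure_name = vapply(key$structure_id, function(i)
      anatomy$terms[[i]]$name, character(1)),
    process_id = key$process_id,
    process_name = vapply(key$process_id, function(i)
      process$terms[[i]]$name, character(1)),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  log_stage("pairs emitted: %d", nrow(pairs))
  structure(pairs, evidence = evidence,
            class = c("structure_process_pairs", "data.frame"))
}

#' @export
print.structure_process_pairs <- function(x, ...) {
  cat("Structure-process pairs:", nrow(x), "\n")
  if (nrow(x)) print.data.frame(x, ...)
  ev <- attr(x, "evidence")
  cat("evidence quadruples:", nrow(ev), "\n")
  invisible(x)
}

#' Write extracted pairs as TSV
#'
#' One row per evidence quadruple, tab-separated with a header line:
#' `structure_id`, `structure_name`, `process_id`, `process_name`,
#' `phenotype_id`, `ancestor_id`, `matched_process_text`,
#' `matched_structure_text`.
#'
#' @param pairs A `structure_process_pairs` object from [extract_pairs()].
#' @param path Output file path or a connection.
#' @return `pairs`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  stopifnot(inherits(pairs, "structure_process_pairs"))
  ev <- attr(pairs, "evidence")
  ev$structure_name <- vapply(ev$structure_id, function(i)
    pairs$structure_name[match(i, pairs$structure_id)], character(1))
  ev$process_name <- vapply(ev$process_id, function(i)
    pairs$process_name[match(i, pairs$process_id)], character(1))
  out <- ev[, c("structure_id", "structure_name", "process_id",
                "process_name", "phenotype_id", "ancestor_id",
                "matched_process_text", "matched_structure_text")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(pairs)
}
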