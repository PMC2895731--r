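# OBO Flatfile Format (1.2 dialect) reading, writing and subsumption queries.
#
# Identifiers are opaque prefixed strings; no ID-space validation is done.
# Only [Term] and [Typedef] stanzas are interpreted; other stanza types are
# skipped with a warning.

#' Construct an ontology term
#'
#' Builds the in-memory representation of one `[Term]` stanza: an ontology
#' category with its identifier, label, synonyms, subsumption parents and
#' other relationships.
#'
#' @param id Prefixed identifier, e.g. `"HP:0000364"`. Must be non-empty.
#' @param name Label text (may be `""`).
#' @param synonyms Data frame with columns `text` and `scope`
#'   (`EXACT`/`BROAD`/`NARROW`/`RELATED`), or `NULL` for none.
#' @param definition Free-text definition, `""` if absent.
#' @param parents Character vector of `is_a` target identifiers.
#' @param relationships Data frame with columns `relation` and `target`,
#'   or `NULL` for none.
#' @param namespace Namespace text, `""` if absent.
#' @param is_obsolete Logical flag; an obsolete term should carry no parents.
#' @param extras Character vector of verbatim `tag: value` lines the parser
#'   does not interpret; preserved on serialization.
#' @return An object of class `obo_term`.
#' @examples
#' obo_term("HP:0000364", "Hearing abnormality", parents = "HP:0000598")
#' @export
obo_term <- function(id, name = "", synonyms = NULL, definition = "",
                     parents = character(), relationships = NULL,
                     namespace = "", is_obsolete = FALSE,
                     extras = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("term id must be a single non-empty string", call. = FALSE)
  if (is.null(synonyms))
    synonyms <- data.frame(text = character(), scope = character(),
                           stringsAsFactors = FALSE)
  if (is.null(relationships))
    relationships <- data.frame(relation = character(), target = character(),
                                stringsAsFactors = FALSE)
  bad <- setdiff(synonyms$scope, c("EXACT", "BROAD", "NARROW", "RELATED"))
  if (length(bad))
    stop("invalid synonym scope: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(id = id, name = name,
         synonyms = synonyms[order(synonyms$text, synonyms$scope), ,
                             drop = FALSE],
         definition = definition,
         parents = sort(unique(as.character(parents))),
         relationships = relationships[order(relationships$relation,
                                             relationships$target), ,
                                       drop = FALSE],
         namespace = namespace,
         is_obsolete = isTRUE(is_obsolete),
         extras = as.character(extras)),
    class = "obo_term")
}

#' Construct an ontology
#'
#' Assembles parsed or programmatically built terms into an `obo_ontology`:
#' header metadata, terms indexed by id, typedef declarations, and the list
#' of parent identifiers that do not resolve to any term (dangling
#' references, kept rather than erroring because real ontology exports
#' occasionally contain them).
#'
#' @param terms List of [obo_term] objects.
#' @param header Named list of header `tag: value` entries.
#' @param typedefs List of typedef declarations as returned by the parser
#'   (each a list with at least `id`, `name`, `holds_over_chain`, `extras`).
#' @return An object of class `obo_ontology`. Terms are stored sorted by id;
#'   duplicate ids are an error.
#' @examples
#' ont <- obo_ontology(list(obo_term("X:1", "root"),
#'                          obo_term("X:2", "leaf", parents = "X:1")))
#' ont$dangling
#' @export
obo_ontology <- function(terms = list(), header = list(), typedefs = list()) {
  ids <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate term id: ", dup, call. = FALSE)
  }
  terms <- terms[order(ids)]
  names(terms) <- sort(ids)
  if (length(header))
    header <- header[order(names(header))]
  referenced <- unique(unlist(lapply(terms, function(t) t$parents),
                              use.names = FALSE))
  dangling <- sort(setdiff(referenced, names(terms)))
  structure(list(header = header, terms = terms, typedefs = typedefs,
                 dangling = dangling),
            class = "obo_ontology")
}

#' @export
print.obo_ontology <- function(x, ...) {
  cat("OBO ontology:", length(x$terms), "terms,",
      length(x$typedefs), "typedefs\n")
  if (length(x$dangling))
    cat("  dangling parent references:", length(x$dangling), "\n")
  invisible(x)
}

#' @export
print.obo_term <- function(x, ...) {
  cat(sprintf("[Term] %s \"%s\"%s\n", x$id, x$name,
              if (x$is_obsolete) " (obsolete)" else ""))
  invisible(x)
}

# Remove an unquoted "!" comment from one line. A "!" inside a double-quoted
# string is literal, and a backslash escapes the next character.
strip_obo_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  in_quote <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\") {
      i <- i + 2L
      next
    }
    if (ch == "\"") in_quote <- !in_quote
    else if (ch == "!" && !in_quote)
      return(substr(line, 1L, i - 1L))
    i <- i + 1L
  }
  line
}

# Extract the leading double-quoted string of a def:/synonym: value, honouring
# backslash escapes. Returns list(text=, rest=) or NULL if the value does not
# start with a quote.
take_quoted <- function(value) {
  value <- sub("^\\s+", "", value)
  if (!startsWith(value, "\"")) return(NULL)
  chars <- strsplit(value, "", fixed = TRUE)[[1L]]
  out <- character(0)
  i <- 2L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      out <- c(out, chars[i + 1L])
      i <- i + 2L
      next
    }
    if (ch == "\"")
      return(list(text = paste(out, collapse = ""),
                  rest = trimws(substr(value, i + 1L, nchar(value)))))
    out <- c(out, ch)
    i <- i + 1L
  }
  NULL
}

#' Parse an OBO Flatfile document
#'
#' Reads OBO Flatfile text into an [obo_ontology]. Everything after an
#' unquoted `!` on a line is a comment and is removed before tag-value
#' interpretation, so `is_a: GO:0007605 ! hearing` yields the parent
#' `GO:0007605`. Tag lines before the first stanza form the document header.
#' `[Term]` and `[Typedef]` stanzas are interpreted; other stanza types are
#' skipped with a warning. Tags the parser does not model are preserved
#' verbatim per term and survive serialization.
#'
#' @param x Character scalar of OBO text, a character vector of lines, or a
#'   path to an existing file.
#' @return An [obo_ontology].
#' @section Errors: a line that is neither a comment, a stanza header nor a
#'   `tag: value` line raises an error naming the line number, as do a
#'   `[Term]` stanza without an `id` and a duplicated id (both stanza line
#'   numbers are reported).
#' @examples
#' ont <- parse_obo(c("[Term]", "id: GO:0007605",
#'                    "name: sensory perception of sound",
#'                    "synonym: \"hearing\" EXACT []"))
#' ont$terms[["GO:0007605"]]$synonyms
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1L]]
  else as.character(x)

  header <- list()
  terms <- list()
  typedefs <- list()
  first_line_of <- character(0)  # id -> line number of its stanza, for errors

  stanza_type <- NA_character_  # NA until first stanza header
  stanza <- NULL
  stanza_line <- NA_integer_
  warned_other <- FALSE

  finish_stanza <- function() {
    if (is.null(stanza)) return(invisible())
    if (identical(stanza_type, "Term")) {
      if (is.null(stanza$id))
        stop("stanza starting at line ", stanza_line, " has no id tag",
             call. = FALSE)
      if (stanza$id %in% names(first_line_of))
        stop("duplicate id ", stanza$id, " in stanzas at lines ",
             first_line_of[[stanza$id]], " and ", stanza_line, call. = FALSE)
      first_line_of[[stanza$id]] <<- stanza_line
      if (isTRUE(stanza$is_obsolete) && length(stanza$parents)) {
        warning("obsolete term ", stanza$id, " has is_a parents",
                call. = FALSE)
      }
      terms[[length(terms) + 1L]] <<- obo_term(
        id = stanza$id, name = stanza$name %||% "",
        synonyms = if (length(stanza$synonyms))
          do.call(rbind, stanza$synonyms) else NULL,
        definition = stanza$definition %||% "",
        parents = stanza$parents %||% character(),
        relationships = if (length(stanza$relationships))
          do.call(rbind, stanza$relationships) else NULL,
        namespace = stanza$namespace %||% "",
        is_obsolete = isTRUE(stanza$is_obsolete),
        extras = stanza$extras %||% character())
    } else if (identical(stanza_type, "Typedef")) {
      typedefs[[length(typedefs) + 1L]] <<- list(
        id = stanza$id %||% "",
        name = stanza$name %||% "",
        holds_over_chain = stanza$chains %||% list(),
        extras = stanza$extras %||% character())
    }
    stanza <<- NULL
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- strip_obo_comment(lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next

    m <- regmatches(line, regexec("^\\[([A-Za-z_]+)\\]$", line))[[1L]]
    if (length(m)) {
      finish_stanza()
      stanza_type <- m[2L]
      stanza_line <- i
      if (stanza_type %in% c("Term", "Typedef")) {
        stanza <- list()
      } else {
        if (!warned_other)
          warning("ignoring unsupported stanza type [", stanza_type,
                  "] at line ", i, call. = FALSE)
        warned_other <- TRUE
        stanza <- NULL
      }
      next
    }

    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 1L)
      stop("line ", i, " is not a stanza header or tag-value line: ",
           line, call. = FALSE)
    tag <- trimws(substr(line, 1L, colon - 1L))
    value <- trimws(substr(line, colon + 1L, nchar(line)))

    if (is.na(stanza_type)) {              # document header
      header[[length(header) + 1L]] <- value
      names(header)[length(header)] <- tag
      next
    }
    if (is.null(stanza)) next              # inside an ignored stanza type

    if (tag == "id") stanza$id <- value
    else if (tag == "name") stanza$name <- value
    else if (tag == "namespace") stanza$namespace <- value
    else if (tag == "is_obsolete") stanza$is_obsolete <-
        identical(tolower(value), "true")
    else if (tag == "is_a")
      stanza$parents <- c(stanza$parents,
                          strsplit(value, "\\s+")[[1L]][1L])
    else if (tag == "def") {
      q <- take_quoted(value)
      stanza$definition <- if (is.null(q)) value else q$text
    } else if (tag == "synonym") {
      q <- take_quoted(value)
      if (is.null(q)) {
        text <- value
        scope <- "RELATED"
      } else {
        text <- q$text
        first <- strsplit(q$rest, "\\s+")[[1L]][1L]
        scope <- if (!is.na(first) &&
                     first %in% c("EXACT", "BROAD", "NARROW", "RELATED"))
          first else "RELATED"
      }
      stanza$synonyms <- c(stanza$synonyms,
                           list(data.frame(text = text, scope = scope,
                                           stringsAsFactors = FALSE)))
    } else if (tag == "relationship") {
      parts <- strsplit(value, "\\s+")[[1L]]
      if (length(parts) >= 2L)
        stanza$relationships <- c(
          stanza$relationships,
          list(data.frame(relation = parts[1L], target = parts[2L],
                          stringsAsFactors = FALSE)))
    } else if (tag == "holds_over_chain" &&
               identical(stanza_type, "Typedef")) {
      stanza$chains <- c(stanza$chains, list(strsplit(value, "\\s+")[[1L]]))
    } else {
      stanza$extras <- c(stanza$extras, paste0(tag, ": ", value))
    }
  }
  finish_stanza()
  obo_ontology(terms = terms, header = header, typedefs = typedefs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One [Term] stanza in canonical tag order.
serialize_term <- function(t) {
  out <- c("[Term]", paste0("id: ", t$id))
  if (nzchar(t$name)) out <- c(out, paste0("name: ", t$name))
  if (nzchar(t$namespace)) out <- c(out, paste0("namespace: ", t$namespace))
  if (nzchar(t$definition))
    out <- c(out, paste0("def: \"", gsub("\"", "\\\\\"", t$definition),
                         "\" []"))
  if (nrow(t$synonyms))
    out <- c(out, sprintf("synonym: \"%s\" %s []",
                          gsub("\"", "\\\\\"", t$synonyms$text),
                          t$synonyms$scope))
  if (length(t$parents)) out <- c(out, paste0("is_a: ", t$parents))
  if (nrow(t$relationships))
    out <- c(out, sprintf("relationship: %s %s",
                          t$relationships$relation, t$relationships$target))
  if (t$is_obsolete) out <- c(out, "is_obsolete: true")
  c(out, t$extras)
}

#' Serialize an ontology to OBO Flatfile text
#'
#' Writes an [obo_ontology] as OBO Flatfile text. Output is canonical and
#' byte-deterministic: header tags sorted by name (with `format-version`
#' first), terms sorted by id, and within each stanza the fixed tag order
#' `id`, `name`, `namespace`, `def`, `synonym`, `is_a`, `relationship`,
#' `is_obsolete`, then preserved unknown tags. Parsing the output yields an
#' ontology equal to the input.
#'
#' @param ontology An [obo_ontology].
#' @param path Optional file path; when given the text is also written there.
#' @return The OBO document as a single character scalar, invisibly when
#'   `path` is given.
#' @examples
#' cat(serialize_obo(obo_ontology(list(obo_term("X:1", "root")))))
#' @export
serialize_obo <- function(ontology, path = NULL) {
  stopifnot(inherits(ontology, "obo_ontology"))
  hdr <- ontology$header
  if (!"format-version" %in% names(hdr))
    hdr <- c(list(`format-version` = "1.2"), hdr)
  hdr <- hdr[c(which(names(hdr) == "format-version"),
               which(names(hdr) != "format-version"))]
  lines <- paste0(names(hdr), ": ", unlist(hdr))
  for (t in ontology$terms) lines <- c(lines, "", serialize_term(t))
  for (td in ontology$typedefs) {
    block <- c("[Typedef]", paste0("id: ", td$id))
    if (nzchar(td$name)) block <- c(block, paste0("name: ", td$name))
    for (ch in td$holds_over_chain)
      block <- c(block, paste0("holds_over_chain: ", paste(ch, collapse = " ")))
    block <- c(block, td$extras)
    lines <- c(lines, "", block)
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Ancestors of a term in the subsumption graph
#'
#' Transitive closure over `is_a` edges (optionally over additional named
#' relations). Cycles are tolerated: each reachable node is reported once.
#' Dangling parent references are skipped with a warning.
#'
#' @param ontology An [obo_ontology].
#' @param id Identifier of the query term; must resolve.
#' @param include_self Include the query term itself? Default `FALSE`.
#' @param relations Character vector of relation names that participate in
#'   the traversal. Default `"is_a"` only (subsumption); add e.g.
#'   `"part_of"` to traverse those `relationship:` edges as well.
#' @return Character vector of identifiers, sorted.
#' @examples
#' ont <- obo_ontology(list(obo_term("X:1", "root"),
#'                          obo_term("X:2", "mid", parents = "X:1"),
#'                          obo_term("X:3", "leaf", parents = "X:2")))
#' ancestors(ont, "X:3")
#' @export
ancestors <- function(ontology, id, include_self = FALSE,
                      relations = "is_a") {
  stopifnot(inherits(ontology, "obo_ontology"))
  if (!id %in% names(ontology$terms))
    stop("unknown term id: ", id, call. = FALSE)
  parents_of <- function(tid) {
    t <- ontology$terms[[tid]]
    out <- if ("is_a" %in% relations) t$parents else character()
    extra <- setdiff(relations, "is_a")
    if (length(extra) && nrow(t$relationships))
      out <- c(out, t$relationships$target[
        t$relationships$relation %in% extra])
    out
  }
  seen <- character(0)
  frontier <- id
  skipped <- character(0)
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, parents_of), use.names = FALSE))
    missing <- setdiff(nxt, names(ontology$terms))
    skipped <- union(skipped, missing)
    nxt <- setdiff(intersect(nxt, names(ontology$terms)), c(seen, id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(skipped))
    warning("skipped dangling parent reference(s): ",
            paste(sort(skipped), collapse = ", "), call. = FALSE)
  out <- if (include_self) union(seen, id) else seen
  sort(out)
}

#' Descendants of a term in the subsumption graph
#'
#' Transitive closure over reversed `is_a` edges; the counterpart of
#' [ancestors()], used for subtree exclusion and neighborhood lint checks.
#'
#' @inheritParams ancestors
#' @return Character vector of identifiers, sorted.
#' @export
descendants <- function(ontology, id, include_self = FALSE) {
  stopifnot(inherits(ontology, "obo_ontology"))
  if (!id %in% names(ontology$terms))
    stop("unknown term id: ", id, call. = FALSE)
  children_of <- lapply(ontology$terms, function(t) t$parents)
  ids <- names(ontology$terms)
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    nxt <- ids[vapply(children_of,
                      function(p) any(p %in% frontier), logical(1))]
    nxt <- setdiff(nxt, c(seen, id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out <- if (include_self) union(seen, id) else seen
  sort(out)
}
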