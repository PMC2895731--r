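# Label normalization: lowercasing, rule-based English singularization and
# whitespace-delimited containment. The matching in the extraction pattern is
# defined on these normalized token lists.

.lexical_env <- new.env(parent = emptyenv())

#' Singularization rule tables
#'
#' Loads the irregular plural/singular pairs and the invariant-word list used
#' by [singularize()]. Both are plain-text files: the irregular table has one
#' whitespace-separated `plural singular` pair per line, the invariant list
#' one word per line; lines starting with `#` are comments. The defaults
#' shipped with the package can be overridden to adapt the vocabulary.
#'
#' @param irregular_file Path to the irregular-pairs file.
#' @param invariant_file Path to the invariant-words file.
#' @return A list with components `irregular` (named character vector mapping
#'   plural to singular) and `invariant` (character vector).
#' @export
lexical_rules <- function(
    irregular_file = system.file("extdata", "plural_irregular.txt",
                                 package = "anatofun"),
    invariant_file = system.file("extdata", "plural_invariant.txt",
                                 package = "anatofun")) {
  read_words <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  pairs <- strsplit(read_words(irregular_file), "\\s+")
  irregular <- vapply(pairs, `[`, character(1), 2L)
  names(irregular) <- vapply(pairs, `[`, character(1), 1L)
  list(irregular = irregular, invariant = read_words(invariant_file))
}

default_rules <- function() {
  if (is.null(.lexical_env$rules))
    .lexical_env$rules <- lexical_rules()
  .lexical_env$rules
}

#' Singular form of an English word
#'
#' Rule-based singularization, applied token by token during label
#' normalization. The rules are tried in order: irregular table lookup;
#' invariant-word list; words not ending in "s" (or ending in "ss", "us" or
#' "is", which mark Latinate singulars like "uterus" or "pelvis") are
#' returned unchanged; then `-ies` to `-y`, `-uses` to `-us`, epenthetic
#' `-es` after a sibilant (`-sses`, `-xes`, `-zes`, `-ches`, `-shes`), and
#' finally a plain trailing `-s` strip. A total function: any token yields a
#' token, and outputs are fixed points of the rules.
#'
#' @param word Character vector of whitespace-free tokens.
#' @param rules Rule tables from [lexical_rules()]; defaults to the shipped
#'   tables.
#' @return Character vector of singular forms, lowercased.
#' @examples
#' singularize(c("ears", "lobes", "glucagon", "processes", "ovaries"))
#' @export
singularize <- function(word, rules = default_rules()) {
  vapply(word, function(w) singularize_one(tolower(w), rules),
         character(1), USE.NAMES = FALSE)
}

singularize_one <- function(w, rules) {
  hit <- rules$irregular[w]
  if (!is.na(hit)) return(unname(hit))
  if (w %in% rules$invariant) return(w)
  n <- nchar(w)
  if (n < 2L || !endsWith(w, "s")) return(w)
  tail2 <- substr(w, n - 1L, n)
  if (tail2 %in% c("ss", "us", "is")) return(w)
  if (n >= 5L && endsWith(w, "ies"))
    return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n >= 6L && endsWith(w, "uses") &&
      !substr(w, n - 4L, n - 4L) %in% c("a", "e", "i", "o", "u"))
    return(substr(w, 1L, n - 2L))  # Latin -us plural: viruses, fetuses
  if (n >= 5L &&
      (endsWith(w, "sses") || endsWith(w, "xes") || endsWith(w, "zes") ||
       endsWith(w, "ches") || endsWith(w, "shes")))
    return(substr(w, 1L, n - 2L))
  substr(w, 1L, n - 1L)
}

#' Normalize a category label
#'
#' Lowercases a label, treats hyphens as token separators (so "t-cell"
#' yields tokens `t`, `cell`), splits on whitespace, strips punctuation at
#' token edges, and singularizes every token. Normalization is idempotent:
#' normalizing the joined tokens of a normalized label reproduces them.
#'
#' @param label Character scalar (the raw label text).
#' @param rules Rule tables from [lexical_rules()].
#' @return An object of class `normalized_label`: a list with `tokens`
#'   (character vector, possibly empty) and `source` (the input text).
#' @examples
#' normalize_label("Abnormality of the ears")$tokens
#' @export
normalize_label <- function(label, rules = default_rules()) {
  stopifnot(is.character(label), length(label) == 1L)
  txt <- tolower(label)
  txt <- gsub("-", " ", txt, fixed = TRUE)
  tokens <- strsplit(txt, "\\s+")[[1L]]
  tokens <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  tokens <- singularize(tokens, rules)
  structure(list(tokens = tokens, source = label),
            class = "normalized_label")
}

#' @export
print.normalized_label <- function(x, ...) {
  cat(sprintf("\"%s\" -> [%s]\n", x$source, paste(x$tokens, collapse = ", ")))
  invisible(x)
}

as_norm <- function(x, rules = default_rules()) {
  if (inherits(x, "normalized_label")) x else normalize_label(x, rules)
}

#' Whitespace-delimited containment of one label in another
#'
#' Tests whether the needle's tokens occur as a contiguous subsequence of
#' the haystack's tokens. On normalized labels this is the token-level
#' equivalent of "occurs as a substring delimited by whitespaces": "ear"
#' is contained in "abnormality of the ears" (after singularization) but
#' not in "heart", where it is a substring without token boundaries.
#' An empty needle is never contained.
#'
#' @param haystack,needle `normalized_label` objects (raw character labels
#'   are normalized on the fly).
#' @return `TRUE` or `FALSE`.
#' @examples
#' contains_delimited("hearing abnormality", "hearing")  # TRUE
#' contains_delimited("heart", "ear")                    # FALSE
#' @export
contains_delimited <- function(haystack, needle) {
  h <- as_norm(haystack)$tokens
  n <- as_norm(needle)$tokens
  k <- length(n)
  if (k == 0L || k > length(h)) return(FALSE)
  for (start in seq_len(length(h) - k + 1L)) {
    if (all(h[start:(start + k - 1L)] == n)) return(TRUE)
  }
  FALSE
}
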