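# Category-level (CC) and individual-level (II) function relation semantics,
# evaluated over finite instance models.
#
# A category E *has the function* F when every instance of E bears some
# instance of F (the standard pattern for lifting an individual-level
# relation to categories). A function category F is *realized by* the
# process category P when any realization of an instance of F is an
# instance of P — functions need not be realized at all, so the
# quantification runs over the realizations that exist, not over the
# function instances. Their composition, has-function-realized-by, links a
# structure category directly to the process kind that realizes its
# (implicit) function; in OWL2 it is expressible as a property chain.

#' Construct a finite instance model
#'
#' A finite first-order structure for checking the function relations:
#' a set of individuals, category extensions (sets of individuals), and the
#' two individual-level edge sets `has_function` (bearer, function instance)
#' and `realized_by` (function instance, process instance).
#'
#' @param individuals Character vector of individual names.
#' @param extensions Named list mapping category id to a character vector of
#'   member individuals (may be empty).
#' @param has_function Two-column matrix or data frame of
#'   (bearer, function) edges; `NULL` for none.
#' @param realized_by Two-column matrix or data frame of
#'   (function, process) edges; `NULL` for none.
#' @return An object of class `instance_model`.
#' @examples
#' m <- instance_model(
#'   individuals = c("x1", "f1", "p1"),
#'   extensions = list(E = "x1", F = "f1", P = "p1"),
#'   has_function = cbind("x1", "f1"),
#'   realized_by = cbind("f1", "p1"))
#' cc_has_function_realized_by(m, "E", "P")
#' @export
instance_model <- function(individuals, extensions = list(),
                           has_function = NULL, realized_by = NULL) {
  individuals <- as.character(individuals)
  as_edges <- function(x, what) {
    if (is.null(x))
      return(matrix(character(), ncol = 2,
                    dimnames = list(NULL, c("from", "to"))))
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop(what, " edges must have two columns",
                            call. = FALSE)
    storage.mode(x) <- "character"
    dimnames(x) <- list(NULL, c("from", "to"))
    unique(x)
  }
  hf <- as_edges(has_function, "has_function")
  rb <- as_edges(realized_by, "realized_by")
  used <- unique(c(unlist(extensions, use.names = FALSE), hf, rb))
  stray <- setdiff(used, individuals)
  if (length(stray))
    stop("individual(s) not declared: ", paste(stray, collapse = ", "),
         call. = FALSE)
  if (is.null(names(extensions)) && length(extensions))
    stop("extensions must be named by category id", call. = FALSE)
  structure(list(individuals = individuals,
                 extensions = lapply(extensions, as.character),
                 has_function = hf, realized_by = rb),
            class = "instance_model")
}

#' @export
print.instance_model <- function(x, ...) {
  cat("Instance model:", length(x$individuals), "individuals,",
      length(x$extensions), "categories,",
      nrow(x$has_function), "has_function and",
      nrow(x$realized_by), "realized_by edges\n")
  invisible(x)
}

#' Read an instance model from a YAML file
#'
#' Expected keys: `individuals` (list of names), `extensions` (mapping
#' category id to member list), `has_function` and `realized_by` (lists of
#' two-element `[from, to]` edges).
#'
#' @param path Path to a YAML file.
#' @return An [instance_model()].
#' @export
read_instance_model <- function(path) {
  v <- yaml::read_yaml(path)
  to_edges <- function(e) if (length(e))
    do.call(rbind, lapply(e, function(p) c(p[[1L]], p[[2L]]))) else NULL
  instance_model(individuals = unlist(v$individuals),
                 extensions = lapply(v$extensions, unlist),
                 has_function = to_edges(v$has_function),
                 realized_by = to_edges(v$realized_by))
}

ext_of <- function(model, id) {
  if (!id %in% names(model$extensions))
    stop("unknown category id: ", id, call. = FALSE)
  model$extensions[[id]]
}

check_individual <- function(model, x) {
  if (!x %in% model$individuals)
    stop("unknown individual: ", x, call. = FALSE)
}

#' CC-has-function: every instance of E bears an instance of F
#'
#' `TRUE` iff for every individual x in ext(E) there is some y in ext(F)
#' with (x, y) a has_function edge. Vacuously `TRUE` when ext(E) is empty.
#'
#' @param model An [instance_model()].
#' @param E,F Category ids (keys of the model's extensions).
#' @return `TRUE` or `FALSE`.
#' @export
cc_has_function <- function(model, E, F) {
  extE <- ext_of(model, E)
  extF <- ext_of(model, F)
  hf <- model$has_function
  all(vapply(extE, function(x)
    any(hf[, "from"] == x & hf[, "to"] %in% extF), logical(1)))
}

#' CC-realized-by: realizations of F instances are always P instances
#'
#' `TRUE` iff every realized_by edge leaving an instance of F lands in
#' ext(P). A function instance with no realization never falsifies the
#' relation: functions are not necessarily realized.
#'
#' @param model An [instance_model()].
#' @param F,P Category ids.
#' @return `TRUE` or `FALSE`.
#' @export
cc_realized_by <- function(model, F, P) {
  extF <- ext_of(model, F)
  extP <- ext_of(model, P)
  rb <- model$realized_by
  hit <- rb[, "from"] %in% extF
  all(rb[hit, "to"] %in% extP)
}

#' CC-has-function-realized-by: E has some function realized by P
#'
#' `TRUE` iff some category F among the model's extensions satisfies both
#' `cc_has_function(E, F)` and `cc_realized_by(F, P)`. The existential
#' ranges over the categories explicitly present in the model, not over
#' arbitrary sets of individuals (over arbitrary subsets the relation would
#' be trivially satisfiable).
#'
#' @param model An [instance_model()].
#' @param E,P Category ids.
#' @param candidates Category ids over which the intermediate function
#'   category F ranges; defaults to all categories of the model.
#' @return `TRUE` or `FALSE`, with attribute `witness` naming one
#'   satisfying F when `TRUE`.
#' @export
cc_has_function_realized_by <- function(model, E, P,
                                        candidates = names(model$extensions)) {
  ext_of(model, E)
  ext_of(model, P)
  for (f in candidates) {
    if (cc_has_function(model, E, f) && cc_realized_by(model, f, P))
      return(structure(TRUE, witness = f))
  }
  FALSE
}

#' II-has-function-realized-by: x's function is in fact realized by p
#'
#' `TRUE` iff some function instance f has (x, f) a has_function edge and
#' (f, p) a realized_by edge — the individual-level relation holds only for
#' functions that are actually (currently) realized, unlike its
#' category-level counterpart, which also holds for unrealized functions.
#'
#' @param model An [instance_model()].
#' @param x,p Individual names.
#' @return `TRUE` or `FALSE`.
#' @export
ii_has_function_realized_by <- function(model, x, p) {
  check_individual(model, x)
  check_individual(model, p)
  hf <- model$has_function
  rb <- model$realized_by
  fs <- hf[hf[, "from"] == x, "to"]
  any(rb[, "from"] %in% fs & rb[, "to"] == p)
}

#' Emit the property-chain axiom linking structures to realizing processes
#'
#' Produces the OWL2 functional-syntax sub-property-chain axiom stating that
#' has-function composed with realized-by implies has-function-realized-by,
#' together with the equivalent OBO `[Typedef]` stanza using
#' `holds_over_chain`. Output is byte-deterministic.
#'
#' @param has_function,realized_by,chain Property name fragments.
#' @return Character scalar containing both serializations.
#' @examples
#' cat(emit_property_chain_axiom())
#' @export
emit_property_chain_axiom <- function(has_function = "has_function",
                                      realized_by = "realized_by",
                                      chain = "has_function_realized_by") {
  ok <- function(x) is.character(x) && length(x) == 1L &&
    grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
  if (!ok(has_function) || !ok(realized_by) || !ok(chain))
    stop("property names must be identifier fragments", call. = FALSE)
  owl <- sprintf(
    "SubObjectPropertyOf(ObjectPropertyChain(ObjectProperty(:%s) ObjectProperty(:%s)) ObjectProperty(:%s))",
    has_function, realized_by, chain)
  obo <- paste(c("[Typedef]",
                 paste0("id: ", chain),
                 paste0("name: ", gsub("_", " ", chain)),
                 paste0("holds_over_chain: ", has_function, " ", realized_by)),
               collapse = "\n")
  paste0(owl, "\n\n", obo, "\n")
}
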