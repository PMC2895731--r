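# Independent brute-force oracles used to cross-check the implementation.
# They deliberately avoid the code paths they verify: reachability by
# repeated edge expansion instead of graph traversal, containment by offset
# scan, extraction by plain quadruple enumeration, relation checking by
# direct quantifier evaluation.

# transitive-closure ancestor sets by repeated edge expansion to fixpoint
oracle_ancestor_sets <- function(ontology) {
  ids <- names(ontology$terms)
  anc <- lapply(ontology$terms,
                function(t) intersect(t$parents, ids))
  repeat {
    changed <- FALSE
    for (i in ids) {
      grown <- unique(c(anc[[i]],
                        unlist(anc[anc[[i]]], use.names = FALSE)))
      grown <- setdiff(grown, i)
      if (length(grown) != length(anc[[i]])) {
        anc[[i]] <- grown
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(anc, sort)
}

# token containment by enumerating every start offset
oracle_contains <- function(h, n) {
  if (length(n) == 0L || length(n) > length(h)) return(FALSE)
  for (s in seq_len(length(h) - length(n) + 1L))
    if (identical(h[s:(s + length(n) - 1L)], n)) return(TRUE)
  FALSE
}

oracle_term_labels <- function(t) unique(c(t$name, t$synonyms$text))

# plain enumeration of all (C, D, E, F) quadruples checked directly against
# the four pattern conditions plus keyword and exclusion filters; returns
# the sorted "structure|process" pair keys
oracle_extract_keys <- function(phenotype, anatomy, process,
                                config = extraction_config()) {
  tok <- function(lab) normalize_label(lab)$tokens
  anc_sets <- oracle_ancestor_sets(phenotype)

  # excluded processes: roots plus descendants via the ancestor-set oracle
  proc_anc <- oracle_ancestor_sets(process)
  roots <- intersect(config$excluded_process_roots, names(process$terms))
  excluded <- roots
  if (config$exclude_descendants)
    excluded <- c(excluded, names(process$terms)[vapply(
      proc_anc, function(a) any(roots %in% a), logical(1))])

  keys <- character(0)
  for (cid in names(phenotype$terms)) {
    C <- phenotype$terms[[cid]]
    if (C$is_obsolete) next
    c_labels <- tolower(oracle_term_labels(C))
    if (!any(vapply(config$abnormality_keywords, function(k)
      any(grepl(k, c_labels, fixed = TRUE)), logical(1)))) next
    c_toks <- lapply(oracle_term_labels(C), tok)
    for (did in setdiff(names(process$terms), excluded)) {
      D <- process$terms[[did]]
      if (D$is_obsolete) next
      d_hit <- any(vapply(oracle_term_labels(D), function(dl) {
        dt <- tok(dl)
        length(dt) > 0L &&
          any(vapply(c_toks, oracle_contains, logical(1), n = dt))
      }, logical(1)))
      if (!d_hit) next
      ancs <- anc_sets[[cid]]
      if (config$include_self_as_ancestor) ancs <- union(ancs, cid)
      for (eid in ancs) {
        e_toks <- lapply(oracle_term_labels(phenotype$terms[[eid]]), tok)
        for (fid in names(anatomy$terms)) {
          F_ <- anatomy$terms[[fid]]
          if (F_$is_obsolete) next
          f_hit <- any(vapply(oracle_term_labels(F_), function(fl) {
            ft <- tok(fl)
            length(ft) > 0L &&
              any(vapply(e_toks, oracle_contains, logical(1), n = ft))
          }, logical(1)))
          if (f_hit) keys <- c(keys, paste0(fid, "|", did))
        }
      }
    }
  }
  sort(unique(keys))
}

pair_keys <- function(pairs) {
  sort(paste0(pairs$structure_id, "|", pairs$process_id))
}

# all subsets of a character vector
subsets_of <- function(x) {
  out <- list(character(0))
  for (el in x) out <- c(out, lapply(out, c, el))
  out
}

# enumerate instance models over fixed sorts: bearer individuals, function
# individuals (split over n_fcat candidate function categories), one process
# individual pool; returns a list of instance_model objects
enumerate_models <- function(bearers = c("x1", "x2"),
                             funs = c("f1", "f2"),
                             procs = "p1", n_fcat = 2L) {
  all_ind <- c(bearers, funs, procs)
  hf_edges <- expand.grid(from = bearers, to = funs,
                          stringsAsFactors = FALSE)
  rb_edges <- expand.grid(from = funs, to = procs,
                          stringsAsFactors = FALSE)
  models <- list()
  for (extE in subsets_of(bearers)) {
    fcat_exts <- subsets_of(funs)
    fcat_choices <- if (n_fcat == 1L) lapply(fcat_exts, list)
      else unlist(lapply(fcat_exts, function(a)
        lapply(fcat_exts, function(b) list(a, b))), recursive = FALSE)
    for (fc in fcat_choices) for (extP in subsets_of(procs)) {
      for (hf_idx in subsets_of(as.character(seq_len(nrow(hf_edges))))) {
        for (rb_idx in subsets_of(as.character(seq_len(nrow(rb_edges))))) {
          exts <- c(list(E = extE, P = extP),
                    stats::setNames(fc, paste0("F", seq_along(fc))))
          models[[length(models) + 1L]] <- instance_model(
            individuals = all_ind, extensions = exts,
            has_function = if (length(hf_idx))
              as.matrix(hf_edges[as.integer(hf_idx), ]) else NULL,
            realized_by = if (length(rb_idx))
              as.matrix(rb_edges[as.integer(rb_idx), ]) else NULL)
        }
      }
    }
  }
  models
}

# direct evaluation of the quantified composite definition:
# exists F among candidates: (forall x in ext(E) exists y in ext(F):
# has_function(x,y)) and (forall y in ext(F), realized_by(y,p): p in ext(P))
oracle_cc_hfrb <- function(model, E, P, candidates) {
  hf <- model$has_function
  rb <- model$realized_by
  for (f in candidates) {
    extF <- model$extensions[[f]]
    part1 <- TRUE
    for (x in model$extensions[[E]]) {
      ys <- hf[hf[, "from"] == x, "to"]
      if (!any(ys %in% extF)) { part1 <- FALSE; break }
    }
    if (!part1) next
    part2 <- TRUE
    for (y in extF) {
      ps <- rb[rb[, "from"] == y, "to"]
      if (!all(ps %in% model$extensions[[P]])) { part2 <- FALSE; break }
    }
    if (part2) return(TRUE)
  }
  FALSE
}
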