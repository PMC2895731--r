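---
title: "Mining anatomical structure-function candidates from phenotype ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining anatomical structure-function candidates from phenotype ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatofun)
```

## The problem and the method

Phenotype ontologies classify abnormal *functionings* (processes that
realize a function going wrong) underneath abnormalities of the structure
that bears the function: "Hearing abnormality" sits under "Abnormality of
the ears". That taxonomic habit encodes, implicitly, which anatomical
structure's function is realized by which biological process. `anatofun`
makes the encoding explicit. The extractor scans a phenotype ontology for
terms C that (i) describe abnormalities (keyword filter), (ii) mention a
process category D in their label, and (iii) sit under an ancestor E whose
label mentions an anatomy category F; each such configuration yields the
candidate assertion *F has-function-realized-by D*.

The method's central assumption is therefore **naming discipline**: that
curators name functional abnormalities compositionally ("abnormal" +
structure + process) and file them under structural abnormalities. Where
that assumption fails — disease eponyms, part/whole shortcuts (an ear
abnormality term standing in for a malfunction of one of its parts),
polysemous process/state words — the extractor produces false positives or
misses. That is why the output carries a full evidence chain per pair and
why the package bundles a lint pass: the pairs are review input, not
assertions.

## Matching: normalization and containment

All label matching happens on normalized token lists:

1. lowercase, treat hyphens as separators (so "t-cell apoptosis" tokenizes
   as `t cell apoptosis`, matching labels written with or without the
   hyphen), split on whitespace, strip punctuation at token edges;
2. singularize each token.

"Occurs as a substring delimited by whitespaces" is then implemented as
*contiguous token-subsequence* containment. After singularization this is
the only faithful reading of whitespace delimitation: raw substring offsets
no longer exist once "ears" has become "ear". It keeps the crucial
asymmetry that "ear" occurs in "abnormality of the ears" but not in
"heart".

Singularization is an ordered rule table rather than a statistical stemmer,
because every transformation must be auditable when a match is reviewed:

| order | rule | example |
|---|---|---|
| 1 | irregular table (shipped, overridable) | teeth → tooth, testes → testis |
| 2 | invariant list (shipped, overridable) | species, pancreas, vas |
| 3 | no trailing `s`, or ends `ss`/`us`/`is` → unchanged | glucagon, process, uterus, pelvis |
| 4 | `-ies` → `-y` (length ≥ 5) | arteries → artery |
| 5 | consonant + `-uses` → `-us` | viruses → virus (but houses → house via rule 7) |
| 6 | `-sses`/`-xes`/`-zes`/`-ches`/`-shes` → strip `es` | boxes → box, branches → branch |
| 7 | strip trailing `-s` | ears → ear |

The `ss`/`us`/`is` guard in rule 3 protects Latinate singulars; the
consonant condition in rule 5 separates Latin `-us` plurals from English
`-se` stems. Known residual weakness: English `-e`-stem sibilant words
("ache"/"aches") would lose their `e` under rule 6; none occur in the
shipped vocabulary, and the irregular table is the escape hatch. The rules
are verified against a shipped reference list of ~200 plural/singular
pairs, and idempotence (singular forms are fixed points) is tested on all
outputs.

## Tunable parameters

* `abnormality_keywords` (default `abnormal`, `impaired`, `decreased`,
  `increased`): matched as **character substrings** of lowercased labels,
  not tokens, because "abnormal" must admit "abnormality". The filter's job
  is to exclude disease-named categories ("Deafness") that would otherwise
  inject diagnostic vocabulary into the function skeleton. Removing a
  keyword can only shrink the output (tested as a monotonicity property).
* `excluded_process_roots` (default GO:0032502 developmental process,
  GO:0043473 pigmentation, GO:0001503 ossification) with
  `exclude_descendants = TRUE`: these labels name both a process and the
  resulting state ("skull ossification" describes a state of the skull,
  not an ongoing process), and the polysemy pervades their subtrees, so the
  default closes over `is_a` descendants. `exclude_descendants = FALSE`
  restores root-only exclusion for comparison.
* `include_self_as_ancestor` (default `FALSE`): the pattern names distinct
  C and E, so a term is not its own ancestor. Setting it to `TRUE` admits
  single-label configurations like "abnormal pancreas insulin secretion",
  where structure and process share one label.
* `synonym_scopes_used` (default all of EXACT/BROAD/NARROW/RELATED): the
  pattern conditions say "name or synonym" without restriction; narrowing
  to EXACT is available when BROAD/RELATED synonyms prove too noisy.
* When several labels of one process term match, the longest matched text
  (most tokens, then most characters) is kept for that term's evidence;
  matches against *different* process terms are all kept, and
  deduplication happens at pair level only — nested names like "hearing"
  inside a longer synonym are genuinely different candidate processes.

Degenerate inputs are defined rather than crashed on: empty ontologies
yield empty outputs; `is_a` cycles are tolerated in traversal (each node
visited once) and left to lint; dangling parent references are recorded at
parse time and skipped with a warning during traversal; obsolete terms
never participate in filtering or matching.

## Relation semantics over finite models

The category-level relations are checked extensionally over
`instance_model` objects — finite sets of individuals, category extensions
and two edge sets. Two semantic decisions matter:

* **CC-realized-by quantifies over realizations, not function instances.**
  A function instance with no `realized_by` edge never falsifies the
  relation; functions can exist unrealized (the deaf ear keeps its hearing
  function). This is what separates the category-level composite from its
  individual-level counterpart, and the test suite constructs a model where
  `cc_has_function_realized_by` holds while `ii_has_function_realized_by`
  is false for every individual pair.
* **The existential in the composite ranges over categories present in the
  model**, not over arbitrary subsets of individuals. Over arbitrary
  subsets the relation is trivially satisfiable (pick exactly the linking
  function instances), which would make it useless as a modelling check.
  The `candidates` argument makes the range explicit.

Verification enumerates the full model family with two bearer individuals,
two function individuals split over two candidate function categories, and
one process individual — 8192 models, every subset of every edge relation —
and compares the implementation against a direct transcription of the
quantified definitions. Larger sorts add nothing semantically (the
definitions are universally/existentially quantified with no counting), so
the family size was chosen to keep exhaustive enumeration exact and fast;
randomized larger models back the II-composition check.

The OWL2 rendering (`emit_property_chain_axiom()`) is a sub-property-chain
axiom — the composite relation subsumes has-function composed with
realized-by — emitted both in functional syntax and as an OBO `[Typedef]`
with `holds_over_chain`, for use in ontologies whose OWL individuals are
themselves ontological categories.

## Lint rules

The four rules target label pathologies that this very extraction method
trips over. Two of them needed sharper definitions than "equal labels":

* **R1 (plural mixing)** fires when a term and an `is_a`
  ancestor/descendant share a word used in singular form in one label and
  plural in the other ("abnormal ear lobe" / "absent ear lobes"). The
  comparison is token-level, not whole-label: the motivating cases differ
  in their leading qualifier, so requiring whole normalized labels to be
  equal would never fire on them. Comparison is restricted to `is_a`
  neighborhoods; unrelated terms legitimately differ in number.
* **R2 (disjunctive labels)** fires on a standalone token "or"
  ("abnormality of tear glands OR tear production") — such labels mix a
  structural and a functional abnormality in one category and should be
  split.
* **R3 ("absent" as quality)** fires on labels beginning with "absent" and
  on definitions or preserved tags referencing PATO:0000462. "Absent" is
  not a quality: a quality needs a bearer, and the meaning of "absent" is
  that the bearer does not exist. The rule deliberately fires for
  structure-style ("absent nipple") and process-style ("absent hearing")
  terms alike.
* **R4 (permuted labels)** fires when two distinct terms carry labels that
  are word-permutation variants ("impaired hearing" vs "hearing
  impairment"). Token multisets are compared after a light derivational
  stem (strip one of `-ing`, `-ed`, `-ment`, `-ness`, `-ance`, `-ence`,
  `-ity`, `-ation` on top of singularization, minimum stem length 3):
  plain singularization cannot equate "impaired" with "impairment", which
  is precisely the inconsistency the rule exists to catch. The stem is a
  heuristic and is used nowhere in extraction — only to group lint
  candidates.

All findings are warnings: each one is a curation suggestion, not a formal
error. One known non-target: process/state polysemy ("ossification",
"pigmentation") is not lexically detectable from a single label; the
practical remedy is suffixing labels with "process" or "state", which is a
curation decision, so the package only excludes the known polysemous
subtrees from extraction and does not attempt a lint rule.

## What the synthetic fixtures do and do not show

`make_worked_example_fixture()` reassembles the hearing configuration and
the lint examples from real HPO/MPO/GO/FMA identifiers; it is deterministic
and is the package's smallest end-to-end input.

`make_random_fixture(seed, n_pairs, n_distractors)` plants pattern
instances — C named "&lt;keyword&gt; &lt;structure&gt; &lt;process&gt;"
under E named "abnormality of the &lt;structure-plural&gt;" — together
with four distractor kinds, one per pattern condition: a keyword-free
phenotype term, a process name concatenated without a token boundary, a
process parked under an excluded root, and an anatomy word present only in
a non-ancestor term. Structure and process words mix real anatomical and
physiological vocabulary (pancreas, uterus, coagulation, lactation,
angiogenesis, ...) with pronounceable nonsense tokens, each word used at
most once per fixture and single-token by construction, so planted truth
is exact and every filter is independently falsifiable. Default generator
shape is 3 planted pairs and 4 distractors (one of each kind), giving
ontologies of roughly 10-20 terms each; verification sweeps 100 seeds and,
separately, varies the pair count from 1 to 5.

What passing these fixtures does **not** show: real phenotype labels are
longer and messier (multi-word anatomy, nested process names, shared
substrings across sibling structures), real ontologies carry multiple
parents and tens of thousands of terms, and real synonym sets are noisy.
The oracle-equivalence test covers correctness of the *algorithm* for any
input; fixture realism bounds only how much the *planted-recovery* numbers
say about precision and recall on real releases — on real data, precision
is limited by the naming-discipline assumption, not by the matcher.

## Numerical and ordering choices

Serialization is canonical — header tags sorted with `format-version`
first, terms sorted by id, fixed tag order within a stanza — so output is
byte-deterministic and parse∘serialize is the identity on the parsed
representation. Extraction output is ordered by (structure id, process id)
with evidence rows ordered within pairs; lint findings by (rule, term ids).
The random generator isolates its RNG state from the caller's and is fully
determined by its seed. There are no floating-point computations anywhere
in the pipeline, so no tolerances are involved; all comparisons are exact.

## Limitations

* Only `is_a` feeds ancestor traversal by default; `part_of` decomposition
  of functions (an ear's function realized by a *part* of a hearing
  process) is out of scope, though named relations can be added to the
  traversal via the `relations` argument of `ancestors()`.
* The extractor matches names and synonyms, not definitions.
* Matching is monolingual English; singularization tables would need
  replacing for other languages.
* The relation checker is a finite-model evaluator, not a reasoner: it
  decides the defined relations over explicit extensions and makes no
  attempt at first-order inference or upper-ontology axiomatics.
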