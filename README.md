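# anatofun

Anatomy ontologies describe what structures *are*; biological-process
ontologies describe what *happens*; phenotype ontologies describe what goes
*wrong*. None of them states explicitly which process realizes the function
of which anatomical structure — there is no public ontology of anatomical
functions. Yet that information is latent in phenotype ontologies such as
HPO and MPO: abnormal *functionings* ("Hearing abnormality") are routinely
classified under abnormalities of the *function-bearing structure*
("Abnormality of the ears"). `anatofun` mines that latent signal. It is a
toolkit for ontology engineers and biocurators who want a machine-harvested
skeleton of structure–function assertions to review, plus the formal
relation semantics needed to assert them soundly, plus a lint pass for the
label pathologies that break this kind of mining.

## The extraction pattern

Given a phenotype ontology, an anatomy ontology and a biological-process
ontology (all in OBO Flatfile Format), the extractor searches for quadruples
(C, D, E, F) such that

1. C is a phenotype category whose name or a synonym contains one of the
   abnormality keywords `abnormal`, `impaired`, `decreased`, `increased`
   as a substring (this drops disease-named categories like "Deafness");
2. the name or a synonym of a process category D occurs in a label of C,
   delimited by whitespace ("hearing" in "Hearing abnormality", but *not*
   "ear" in "heart");
3. E is an `is_a` ancestor of C;
4. the name or a synonym of an anatomy category F occurs
   whitespace-delimited in a label of E ("ear" in "Abnormality of the
   ears").

Each quadruple yields the candidate pair (F, D): *structure F has some
function that is realized by processes of kind D*. Before matching, all
labels are lowercased and every token is reduced to its English singular
form by an auditable rule table, so "ears" matches "Ear". Process terms
under `developmental process` (GO:0032502), `pigmentation` (GO:0043473) and
`ossification` (GO:0001503) are excluded by default — their labels are
polysemous between a process and the state it produces.

The pair is read through a category-level relation,
**has-function-realized-by**: E bears some function category whose
realizations, when they occur, are instances of P. Its two constituents are

- **CC-has-function(E, F)** — every instance of E bears an instance of F;
- **CC-realized-by(F, P)** — every realization of an instance of F is an
  instance of P (a function may exist *unrealized*, so unrealized function
  instances never falsify this).

`anatofun` evaluates these definitions over finite instance models
(`instance_model()`, `cc_has_function()`, `cc_realized_by()`,
`cc_has_function_realized_by()`, `ii_has_function_realized_by()`) and emits
the corresponding OWL2 property-chain axiom
(`emit_property_chain_axiom()`). The distinction between the category-level
and the individual-level composite is real: a structure category can stand
in the relation while no actual realization exists anywhere in the model —
a malfunctional bearer retains its function.

## Worked example

```r
library(anatofun)

fx <- make_worked_example_fixture()   # miniature HPO/FMA/GO triple
extract_pairs(fx$phenotype, fx$anatomy, fx$process)
#> Structure-process pairs: 1 
#>   structure_id structure_name process_id                process_name
#> 1    FMA:52780            Ear GO:0007605 sensory perception of sound
#> evidence quadruples: 1 
```

One pair is found: the ear's function is realized by sensory perception of
sound (GO:0007605, synonym "hearing"). The evidence attribute records the
chain that produced it — "Hearing abnormality" (HP:0000364) matched the
process synonym, and its ancestor "Abnormality of the ears" (HP:0000598)
matched the anatomy term — so every pair can be audited back to the
phenotype terms that imply it.

The same fixture exercises the lint rules:

```r
run_lint(fx$phenotype)[, c("rule", "term_ids")]
#>   rule              term_ids
#> 1   R1 MP:0003677,MP:0003678   # "abnormal ear lobe" vs "absent ear lobes"
#> 2   R2            HP:0000251   # "... tear glands OR tear production"
#> 3   R3            MP:0001967   # PATO:0000462 "absent" used as a quality
#> 4   R3            MP:0003678
#> 5   R4 HP:0000364,MP:0001965   # permuted label variants
#> 6   R4 MP:0001965,MP:0006325   # "hearing impairment"/"impaired hearing"
```

A thin CLI wraps the same functions:

```sh
exec/anatofun fixture --kind worked --out-dir /tmp/fx
exec/anatofun extract --phenotype /tmp/fx/phenotype.obo \
    --anatomy /tmp/fx/anatomy.obo --process /tmp/fx/process.obo
exec/anatofun lint /tmp/fx/phenotype.obo
```

## Running on current ontology releases

The package ships no ontology data; to mine real releases, download the
OBO exports and run the extractor directly (this is deliberately not part
of the test suite — it needs network access and several hundred megabytes):

```sh
curl -LO http://purl.obolibrary.org/obo/hp.obo       # phenotype (human)
curl -LO http://purl.obolibrary.org/obo/go.obo       # biological process
curl -LO http://purl.obolibrary.org/obo/uberon.obo   # anatomy (or ma.obo for mouse)

exec/anatofun extract --phenotype hp.obo --anatomy uberon.obo \
    --process go.obo --out pairs.tsv
exec/anatofun lint hp.obo --out findings.tsv
```

For mouse, pair `mp.obo` with `ma.obo`. Expect run time of minutes and an
output of tens to hundreds of candidate pairs depending on the release.
Pair counts are **not** stable across ontology releases: labels, synonyms
and subsumption links are continually revised, so counts from any earlier
snapshot of these ontologies will not reproduce on current files, and every
emitted pair is a *candidate* that needs manual review (the evidence
columns in `pairs.tsv` exist for exactly that purpose).

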