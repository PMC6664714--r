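# owlet

An ontology-workflow toolkit for the OBO-style release cycle, written in
R with its own lightweight OWL data model and a built-in EL reasoner.
It is aimed at ontology developers and bioinformaticians who need to
run — or script, or test — the standard pipeline

```
verify  →  extract imports  →  reason  →  relax  →  reduce  →  annotate  →  convert
```

without a Java stack, an external reasoner, or a web service.

## What it does

* **IO** — read/write Turtle, RDF/XML and OBO flat-file 1.4 (a defined
  subset), with byte-deterministic serialization; import resolution
  through a local catalog only (no network).
* **Reasoning** — saturation-based classification for the EL fragment
  (named classes, `R some C`, intersections) plus class disjointness.
  Axioms are normalized to the forms `A ⊑ B`, `A1 ⊓ A2 ⊑ B`,
  `A ⊑ ∃R.B`, `∃R.B ⊑ A`, and the standard completion rules run to
  fixpoint; `disjoint(B,C)` compiles to `B ⊓ C ⊑ ⊥`, and a class
  subsumed by `⊥` is unsatisfiable.  `reason()` validates coherence
  (halting with the unsatisfiable classes named) and asserts all direct
  inferred `subClassOf` axioms.
* **Axiom calculus** — `relax()` (equivalence conjuncts as subclass
  edges), `reduce()` (redundant-edge removal), `materialize()`
  (entailed `A ⊑ R some B` with most-specific fillers).
* **Extraction** — MIREOT (bottom terms + ancestors up to top terms)
  and syntactic-locality modules (BOT/TOP/STAR) with
  `--annotate-with-source` provenance.
* **Document algebra** — `merge` (with import-closure collapse),
  `remove`/`filter` with selectors (self, ancestors, descendants,
  annotation value/regex, entity type), `annotate` (version IRI +
  header annotations), axiom-level `diff`.
* **SPARQL** — SELECT/ASK/CONSTRUCT/UPDATE over the document's RDF
  view (imports optionally as named graphs), delegated to Python rdflib
  through a subprocess bridge; `verify` with the 0-rows-is-success exit
  contract.
* **QC report** — a configurable battery of checks at ERROR/WARN/INFO
  levels with fail-on logic and TSV/CSV/YAML output, plus `repair` for
  duplicate-axiom annotation merging and deprecated-reference
  rewriting.
* **Templates** — TSV/CSV tables with `ID`/`LABEL`/`TYPE`/`A p`/
  `SC %`/`EC %` template strings expand into ontology modules.
* **Synthetic fixtures** — a seeded generator of ground-truth
  ontologies (DAG taxonomy, logical definitions, injected QC-violation
  census, import chains) with a ledger computed by independent
  algorithms; this is what the test suite measures everything against.

## Worked example

```r
library(owlet)

fx <- generate_fixture(fixture_spec(n_classes = 12, n_properties = 2,
                                    p_existential = 0.4, seed = 7,
                                    violation_census = list(missing_label = 1)))
fx
#> <owlet_fixture> 12 classes, 14 asserted edges, 0 import(s)

rep <- run_report(fx$doc)
rep
#> <owlet_report> 1 violation(s) (ERROR: 1)  failed: TRUE
rep$violations[, c("level", "rule", "subject")]
#>   level          rule                     subject
#> 1 ERROR missing_label http://example.org/fx/C0005
```

The report found exactly the injected violation: one class without an
`rdfs:label`, an ERROR-level finding, so a release run would stop here.
Fixing it (or setting `fail_on = "none"`) lets the release sequence
proceed:

```r
released <- annotate_document(reduce(relax(reason(fx$doc))),
  version_iri = "http://example.org/fx/2026-01-01/fixture.owl")
diff_documents(fx$doc, released)
#> 2 axiom(s) only in left:
#> - sub(<http://example.org/fx/C0006>,<http://example.org/fx/C0003>)
#> - sub(<http://example.org/fx/C0007>,<http://example.org/fx/C0003>)
#> 2 axiom(s) only in right:
#> + sub(<http://example.org/fx/C0003>,some(<http://example.org/fx/P1>,<http://example.org/fx/C0002>))
#> + sub(<http://example.org/fx/C0004>,some(<http://example.org/fx/P2>,<http://example.org/fx/C0002>))
```

Reading the diff: `relax` asserted two existential superclasses taken
from equivalence definitions (so browsers can navigate them without a
reasoner), and `reduce` removed two asserted edges that had become
redundant — each is still entailed through a named intermediate.
`write_document(released, "release.obo", lossy = TRUE)` then emits the
OBO release product.

The same pipeline from a shell, as one chained command:

```sh
owlet reason --input edit.ttl relax reduce \
      annotate --version-iri http://example.org/fx/2026-01-01/fixture.owl \
      --output release.ttl
```

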