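---
title: "Ontology release workflows with owlet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology release workflows with owlet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlet)
```

## What owlet is for

Biomedical ontologies are released through pipelines, not saved from an
editor: the editors' file is quality-checked, import modules are
regenerated from term lists, the ontology is classified by a reasoner,
redundant axioms are cleaned up, version metadata is stamped, and release
artifacts are serialized in several formats.  owlet packages these steps
as composable R functions and a chainable command line, over its own
lightweight OWL data model and built-in reasoner, so a complete release
workflow runs with no external reasoner, Java stack or web service.

The in-memory unit is the *ontology document*: an ontology IRI and
version IRI, a prefix map, an import list, ontology-level annotations,
and a duplicate-free set of axioms.  Two axioms with the same logical
content but different axiom annotations are distinct members of the set —
the distinction that makes "duplicate axioms" repairable.  All commands
read and return documents, so chains like
`merge |> reason |> relax |> reduce |> annotate |> convert` thread one
object through memory and only serialize where an output is requested.

## The logic fragment and the reasoner

owlet deliberately supports the EL-style fragment that large biomedical
ontologies live in: named classes, existential restrictions
(`R some C`), intersections, subclass and equivalence axioms, class
disjointness, and object-property hierarchies at the assertion level.
Anything outside this grammar (unions, universal restrictions,
cardinalities, inverse properties, ...) is rejected with an error naming
the construct — never silently dropped.  This profile admits
polynomial-time classification, which is what makes an embedded reasoner
practical.

Classification normalizes axioms by giving every complex subexpression a
definitional auxiliary name (a conservative extension; the names are the
canonical expression rendering in a reserved `urn:` namespace, so runs
are reproducible), leaving four normal forms, then runs the standard
completion rules to fixpoint over a boolean subsumption matrix.
Disjointness `disjoint(B, C)` compiles to `B ⊓ C ⊑ ⊥`; a class subsumed
by `⊥` is unsatisfiable.  The taxonomy reported by `classify()` contains
equivalence groups (canonical representative: the lexicographically
least IRI), transitively reduced direct edges, and the unsatisfiable
set.  `reason()` implements the release contract: if the ontology is
incoherent it halts with an error listing the unsatisfiable classes;
otherwise every direct inferred named subsumption that is not already
asserted is added (never edges to `owl:Thing`).  Property hierarchies do
not participate in existential subsumption; this keeps classification
within the matrix fragment and is a documented restriction.

Correctness is checked against an independent oracle,
`naive_entailed_subsumptions()`: an exhaustive expression-level closure
(reflexivity, transitivity, intersection introduction/elimination,
existential monotonicity, disjointness clash, bottom propagation) that
shares no code or normal forms with the saturation reasoner.  The test
suite and the acceptance script compare the two on hundreds of seeded
random ontologies, demanding exact agreement on subsumptions, direct
edges and unsatisfiable sets.

```{r reason-example}
fx <- generate_fixture(fixture_spec(n_classes = 12, n_properties = 2,
                                    p_existential = 0.4, seed = 7))
tax <- classify(fx$doc)
tax
head(tax$direct_edges)
```

## relax, reduce, materialize

`relax()` turns each equivalence `A ≡ C1 ⊓ ... ⊓ Cn` into explicit
`A ⊑ Ci` edges so downstream consumers can navigate without a reasoner.
`reduce()` then removes redundant subclass edges.  Redundant here means
*indirectly* entailed: the edge survives deletion because a strict named
intermediate carries it, or because its endpoints are equivalent.  An
edge that is a direct subsumption is kept even when an equivalence
definition also entails it — otherwise reduce would undo exactly what
relax asserted, and the relax-then-reduce release step would be a no-op.
Candidates are processed in lexicographic (sub, sup) order with
re-checking after each removal, so interacting redundancies resolve
deterministically.  `materialize()` asserts entailed anonymous
superclasses `A ⊑ R some B` with most-specific named fillers (ties
between equivalent fillers keep the lexicographically least), for
selected properties or all of them.

## Module extraction

`extract_mireot()` implements the minimal-information import strategy:
the requested bottom terms plus their ancestors along asserted named
subclass edges, stopping at (and including) any top terms, copying only
declarations, labels, definitions and the retained edges.
`extract_slme()` implements syntactic-locality modules: an axiom is
*local* w.r.t. a signature if replacing its out-of-signature symbols by
`⊥` (BOT) or `⊤` (TOP) makes it a tautology; non-local axioms join the
module and grow the signature until fixpoint.  STAR alternates BOT and
TOP extraction to a fixpoint and is therefore a subset of both.  BOT
modules preserve every entailment over the seed signature — the suite
checks this against the naive closure oracle.

## SPARQL, verify and the QC report

The document's RDF view follows the standard OWL-to-RDF mapping
(restrictions and intersections as blank nodes, axiom annotations via
the `owl:Axiom` reification pattern, n-ary disjointness via
`owl:AllDisjointClasses`).  SPARQL execution is delegated to the host
RDF stack — Python rdflib through a small subprocess bridge exchanging
N-Triples and SPARQL-JSON — while owlet owns the document↔graph mapping,
deterministic row ordering, and the exit-code contract.  With
`use_graphs`, resolved imports are exposed as named graphs keyed by
their ontology IRIs and the default graph is the union of all graphs.

`verify_queries()` runs SELECT queries written so that any returned row
is a violation: status 0 iff every query returns zero rows, otherwise
status 1 with each offending query's rows dumped as CSV.  A query that
fails to parse is a usage error (status 2), not a violation.

`run_report()` executes the built-in QC battery (all SPARQL checks in a
single engine invocation).  Severity levels: **ERROR** for
missing/duplicate labels and definitions, **WARN** for inferred
equivalent class pairs, self references, trailing whitespace, invalid
cross-reference syntax (`PREFIX:LOCAL`, nonempty parts, no whitespace)
and missing ontology license/title, **INFO** for definition style
(uppercase start, terminal period) and missing definitions.  The
equivalent-pair check consumes the reasoner's taxonomy, so *inferred*
equivalences are caught, not just asserted ones.  Profiles can override
levels, exclude checks, add custom SPARQL checks
(`LEVEL<TAB>name<TAB>query-path` lines) and set the failure threshold;
the default fails on ERROR.

`repair_document()` fixes the two mechanical problems: duplicate axioms
(same logical content) are collapsed into one axiom carrying the union
of their annotations, and logical references to deprecated classes with
a replacement annotation are rewritten to the transitively resolved
replacement (cycles are errors; annotations on the deprecated terms are
kept).

## Templates

`parse_template()` / `expand_template()` turn a TSV/CSV table into an
ontology module.  Row 1 is human column labels (ignored), row 2 holds
template strings — `ID`, `LABEL`, `TYPE`, `A <property>`, `SC %`,
`SC R some %`, `EC %`, `EC R some %` — and rows 3+ are terms.  Only this
subset is supported and anything else is rejected loudly; cell values in
class positions are CURIEs/IRIs, never labels.  Expansion is
deterministic and row-order independent at the axiom-set level, so a
template module merged into the editors' file reproduces the
template→merge→reason release path.

## Serialization and determinism

Turtle, RDF/XML and OBO 1.4 writers are pure functions of the document:
prefixes sorted by name, axioms sorted by (variant rank, canonical
rendering), blank nodes labelled in emission order.  Writing the same
document twice is byte-identical, which is what makes chained and
stepwise pipelines comparable at the file level and keeps version-control
diffs clean.  `diff_documents()` nevertheless compares axiom *sets*, not
text, so serialization noise can never masquerade as a change.

The OBO-expressible subset is: Term/Typedef declarations, `name`,
`def` (with cross-reference list), `subset`, `xref`, `is_a` between
named classes, `relationship:` for `A ⊑ R some B`, `equivalent_to` for
named or genus-differentia (`intersection_of`) equivalences,
`is_obsolete`, `replaced_by`.  Values carrying language tags or
datatypes (other than boolean `true` for obsoletion) are not
expressible, since OBO tags cannot round-trip them.  Writing a document
with non-expressible axioms is an error by default; `lossy = TRUE`
restricts to the expressible subset, which is exactly what the `convert`
command does for OBO release products.  The version IRI travels
verbatim in the `data-version:` header line.  One mapping caveat: n-ary
equivalence axioms serialize to RDF as a sorted chain of binary
`owl:equivalentClass` triples and read back as binary axioms; and a bare
axiom cannot be distinguished from its annotated duplicate in RDF, so
duplicate axioms survive a round trip only when each copy is annotated
(which is how they arise in practice).

## The synthetic-fixture generator

`generate_fixture()` is first-class, tested code, not a test utility:
it produces the ground-truth ontologies every higher-level contract is
measured against.  A fixture is a rooted DAG (each class draws 1–2
parents among earlier classes — acyclic by construction, single root)
of `n_classes` classes (default 20) with unique labels and
period-terminated definitions, `n_properties` object properties
(default 3), and genus-differentia equivalence definitions on a
`p_existential` fraction of classes (default 0.2), each using a fresh
(genus, property, filler) combination.  The generator rejects
definitions that would make two distinct classes inferred-equivalent by
accident, and selects equivalence-pair violation victims so that the
injected pairs are exactly the inferred ones — otherwise the violation
census would not be ground truth.  Requested violations are injected on
disjoint victim sets drawn without replacement (an infeasible census is
an error); unsatisfiable classes are created as fresh disjointness
clashes; deprecated terms point at their parent as replacement.  The
ledger (asserted edges, entailed closure, expected direct edges,
unsatisfiable set, violation subjects, MIREOT expectations) is computed
by plain reachability and the naive closure — never by the modules under
test.

What the fixtures do not emulate: realistic term-name statistics, OBO
identifier policies, very large ontologies, or axiom kinds outside the
supported fragment.  Passing tests therefore demonstrate correctness of
the algorithms on in-fragment inputs, not robustness to arbitrary
real-world OWL files.

Problem sizes used by the test suite and acceptance script — 200 random
ontologies of up to 12 classes for the reasoner-oracle comparison, a
50-class fixture for the release pipeline, 20 fixture pairs for
chaining, 50 fixtures for census recovery — were chosen so the whole
battery exercises every interaction while remaining a desk-scale,
seconds-to-minutes run.

## Command-line use

The installed `exec/owlet` script exposes the same operations as
chainable commands:

```
owlet merge --input edit.ttl --input imports.ttl \
      reason \
      relax \
      reduce \
      annotate --version-iri http://example.org/fx/2026-01-01/ont.owl \
      --output release.ttl \
      convert --output release.obo --format obo
```

Exit codes: 0 success; 1 check failures (verify rows, report fail-on,
reasoner incoherence, diff differences); 2 usage errors; 3 I/O or parse
errors.  Intermediate `--output` options serialize without breaking the
chain; a failing step stops execution before later steps run.

## Known limitations

* Subsumption reasoning ignores the property hierarchy
  (`sub_property_of` is carried, serialized and filterable, but does not
  feed existential subsumption).
* No ABox: individuals can be declared and annotated, but class
  assertions are outside the grammar.
* `is_entailed()` accepts subclass axioms only; other axiom types would
  need encoding by the caller.
* The SPARQL bridge requires a Python interpreter with rdflib on the
  PATH (override with `options(owlet.python = ...)` or `OWLET_PYTHON`).
* MIREOT retains only labels and definitions by design; additional
  annotation properties are a deliberate non-goal of the minimal
  information principle.
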