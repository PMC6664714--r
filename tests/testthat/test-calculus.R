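# relax / reduce / materialize.

test_that("relax asserts conjunct subclass axioms from definitions", {
  doc <- ontology_document(axioms = list(
    ax_equivalent(list(ce_named(ex("A")),
      ce_and(list(ce_named(ex("B")), ce_some(ex("R"), ex("C"))))))))
  out <- relax(doc)
  keys <- logical_keys(out)
  expect_true(subclass_key("A", "B") %in% keys)
  expect_true(sprintf("sub(<%s>,some(<%s>,<%s>))", ex("A"), ex("R"), ex("C"))
              %in% keys)
  # no equivalences -> unchanged
  plain <- doc_from_edges("A>B")
  expect_identical(axiom_keys(relax(plain)), axiom_keys(plain))
  # named-named equivalence relaxes symmetrically (oracle-confirmed)
  both <- relax(ontology_document(axioms = list(
    ax_equivalent(list(ce_named(ex("A")), ce_named(ex("B")))))))
  expect_true(subclass_key("A", "B") %in% logical_keys(both))
  expect_true(subclass_key("B", "A") %in% logical_keys(both))
  expect_true(oracle_entailed(doc, ce_named(ex("A")), ce_named(ex("B"))))
})

test_that("relax is conservative: everything added is entailed by the input", {
  for (seed in c(3, 8, 14)) {
    fx <- random_fixture(seed)
    out <- relax(fx$doc)
    for (k in setdiff(names(out$axioms), names(fx$doc$axioms))) {
      ax <- out$axioms[[k]]
      expect_true(oracle_entailed(fx$doc, ax$sub, ax$sup),
                  info = sprintf("seed %d: %s", seed, k))
    }
  }
})

test_that("reduce removes transitive redundancy and nothing else", {
  out <- reduce(doc_from_edges("A>B", "B>C", "A>C"))
  expect_identical(logical_keys(out),
                   c(subclass_key("A", "B"), subclass_key("B", "C")))
  plain <- doc_from_edges("A>B")
  expect_identical(axiom_keys(reduce(plain)), axiom_keys(plain))
})

test_that("relax then reduce leaves exactly one conjunct edge", {
  doc <- ontology_document(axioms = list(
    ax_equivalent(list(ce_named(ex("A")),
      ce_and(list(ce_named(ex("B")), ce_some(ex("R"), ex("C")))))),
    ax_subclass(ex("A"), ex("B"))))
  out <- reduce(relax(doc))
  keys <- logical_keys(out)
  expect_identical(sum(keys == subclass_key("A", "B")), 1L)
})

test_that("reduce preserves entailed named subsumptions and is idempotent", {
  for (seed in c(4, 12, 23)) {
    fx <- random_fixture(seed)
    doc <- relax(reason(fx$doc))
    red <- reduce(doc)
    expect_identical(
      subsumption_set(classify(red)$subsumptions),
      subsumption_set(classify(doc)$subsumptions),
      info = sprintf("seed %d", seed))
    expect_identical(axiom_keys(reduce(red)), axiom_keys(red),
                     info = sprintf("seed %d", seed))
  }
})

test_that("materialize asserts most-specific existential superclasses", {
  # inherited existential: A [= B, B [= R some C  =>  A [= R some C
  doc <- ontology_document(axioms = list(
    ax_subclass(ex("A"), ex("B")),
    ax_subclass(ce_named(ex("B")), ce_some(ex("R"), ex("C")))))
  expect_true(oracle_entailed(doc, ce_named(ex("A")),
                              ce_some(ex("R"), ex("C"))))
  out <- materialize(doc)
  expect_true(sprintf("sub(<%s>,some(<%s>,<%s>))", ex("A"), ex("R"), ex("C"))
              %in% logical_keys(out))
  # most-specific filler rule: with C [= D, the D-filler is suppressed
  doc2 <- ontology_document(axioms = list(
    ax_subclass(ce_named(ex("A")), ce_some(ex("R"), ex("C"))),
    ax_subclass(ex("C"), ex("D"))))
  expect_true(oracle_entailed(doc2, ce_named(ex("A")),
                              ce_some(ex("R"), ex("D"))))
  out2 <- materialize(doc2)
  expect_identical(axiom_keys(out2), axiom_keys(doc2))
  # empty ontology unchanged
  empty <- ontology_document()
  expect_identical(axiom_keys(materialize(empty)), axiom_keys(empty))
})

test_that("materialize additions are entailed by the input", {
  for (seed in c(6, 19)) {
    fx <- random_fixture(seed)
    out <- materialize(fx$doc)
    for (k in setdiff(names(out$axioms), names(fx$doc$axioms))) {
      ax <- out$axioms[[k]]
      expect_true(oracle_entailed(fx$doc, ax$sub, ax$sup),
                  info = sprintf("seed %d: %s", seed, k))
    }
  }
})

test_that("materialize honors the property selection and incoherence contract", {
  doc <- ontology_document(axioms = list(
    ax_subclass(ex("A"), ex("B")),
    ax_subclass(ce_named(ex("B")), ce_some(ex("R"), ex("C"))),
    ax_subclass(ce_named(ex("B")), ce_some(ex("S"), ex("C")))))
  out <- materialize(doc, properties = ex("R"))
  keys <- logical_keys(out)
  expect_true(sprintf("sub(<%s>,some(<%s>,<%s>))", ex("A"), ex("R"), ex("C"))
              %in% keys)
  expect_false(sprintf("sub(<%s>,some(<%s>,<%s>))", ex("A"), ex("S"), ex("C"))
               %in% keys)
  bad <- doc_from_edges("A>B", "A>C",
                        extra = list(ax_disjoint(c(ex("B"), ex("C")))))
  expect_error(materialize(bad), class = "owlet_incoherent")
})
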