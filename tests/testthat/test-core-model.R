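# Core model: identifiers, class expressions, axioms, documents,
# signature and axiom-set algebra.

test_that("CURIE expansion and contraction are inverse under a prefix map", {
  pfx <- c(EX = "http://example.org/", GO = "http://purl.obolibrary.org/obo/GO_")
  curies <- c("EX:alpha", "GO:0008150", "EX:a-b_c.d")
  iris <- expand_curie(curies, pfx)
  expect_true(all(startsWith(iris, "http://")))
  expect_identical(contract_iri(iris, pfx), curies)
  # absolute IRIs pass through expansion untouched
  expect_identical(expand_curie("http://x.org/y", pfx), "http://x.org/y")
  # longest prefix wins, ties broken lexicographically by prefix name
  pfx2 <- c(b = "http://x.org/", a = "http://x.org/", long = "http://x.org/sub/")
  expect_identical(contract_iri("http://x.org/sub/leaf", pfx2), "long:leaf")
  expect_identical(contract_iri("http://x.org/leaf", pfx2), "a:leaf")
})

test_that("identifier equality is full-IRI string equality", {
  expect_identical(ce_key(ce_named("http://x/A")), ce_key(ce_named("http://x/A")))
  expect_false(ce_key(ce_named("http://x/A")) == ce_key(ce_named("http://y/A")))
})

test_that("intersections flatten, deduplicate and ignore operand order", {
  a <- ce_named(ex("A")); b <- ce_named(ex("B")); r <- ce_some(ex("R"), a)
  e1 <- ce_and(list(a, ce_and(list(b, r))))
  e2 <- ce_and(list(r, b, a))
  expect_identical(ce_key(e1), ce_key(e2))
  expect_equal(e1$kind, "and")
  expect_length(e1$operands, 3)
  expect_false(any(vapply(e1$operands, function(o) o$kind == "and",
                          logical(1))))
  # single distinct operand collapses
  expect_identical(ce_key(ce_and(list(a, a))), ce_key(a))
})

test_that("axioms separate logical content from axiom annotations", {
  plain <- ax_subclass(ex("A"), ex("B"))
  ann1 <- ax_subclass(ex("A"), ex("B"),
                      anns = list(annotation_pair(iri_label, literal("v"))))
  ann2 <- ax_subclass(ex("A"), ex("B"),
                      anns = list(annotation_pair(iri_label, literal("w"))))
  expect_identical(logical_key(plain), logical_key(ann1))
  expect_identical(logical_key(ann1), logical_key(ann2))
  expect_false(axiom_key(ann1) == axiom_key(ann2))
  # unordered member sets
  expect_identical(
    logical_key(ax_disjoint(c(ex("B"), ex("A")))),
    logical_key(ax_disjoint(c(ex("A"), ex("B")))))
  expect_identical(
    logical_key(ax_equivalent(list(ce_named(ex("B")), ce_named(ex("A"))))),
    logical_key(ax_equivalent(list(ce_named(ex("A")), ce_named(ex("B"))))))
})

test_that("axiom_set_merge is a set union keeping annotated duplicates", {
  x <- list(ax_subclass(ex("A"), ex("B")), ax_declaration(ex("A"), "class"))
  expect_length(axiom_set_merge(x, list()), 2)
  expect_length(axiom_set_merge(x, x), 2)
  ann1 <- ax_subclass(ex("A"), ex("B"),
                      anns = list(annotation_pair(iri_label, literal("v"))))
  ann2 <- ax_subclass(ex("A"), ex("B"),
                      anns = list(annotation_pair(iri_label, literal("w"))))
  expect_length(axiom_set_merge(list(ann1), list(ann2)), 2)
})

test_that("axiom-set union is associative, commutative, idempotent", {
  keyset <- function(axs) sort(vapply(axs, axiom_key, character(1)))
  for (seed in 1:4) {
    a <- random_fixture(seed)$doc$axioms
    b <- random_fixture(seed + 10)$doc$axioms
    c3 <- random_fixture(seed + 20)$doc$axioms
    expect_identical(keyset(axiom_set_merge(a, b)),
                     keyset(axiom_set_merge(b, a)))
    expect_identical(
      keyset(axiom_set_merge(axiom_set_merge(a, b), c3)),
      keyset(axiom_set_merge(a, axiom_set_merge(b, c3))))
    expect_identical(keyset(axiom_set_merge(a, a)), keyset(a))
  }
})

test_that("signature partitions entities by declaration and usage", {
  empty <- signature_of(ontology_document())
  expect_identical(lengths(unclass(empty)),
                   c(classes = 0L, object_properties = 0L,
                     annotation_properties = 0L, individuals = 0L))
  doc <- ontology_document(axioms = list(
    ax_declaration(ex("A"), "class"),
    ax_subclass(ce_named(ex("A")), ce_some(ex("R"), ex("B")))))
  sig <- signature_of(doc)
  expect_setequal(sig$classes, c(ex("A"), ex("B")))
  expect_identical(sig$object_properties, ex("R"))
})

test_that("signature sizes match the fixture generator's entity ledger", {
  fx <- generate_fixture(fixture_spec(n_classes = 20, n_properties = 3,
                                      p_existential = 0.3, seed = 11))
  sig <- signature_of(fx$doc)
  expect_setequal(sig$classes, fx$ledger$classes)
  expect_setequal(sig$object_properties, fx$ledger$properties)
  expect_length(sig$individuals, 0)
})

test_that("incompatible undeclared roles raise a role-conflict error", {
  doc <- ontology_document(axioms = list(
    ax_subclass(ex("A"), ex("X")),
    ax_subclass(ce_named(ex("B")), ce_some(ex("X"), ex("C")))))
  expect_error(signature_of(doc), class = "owlet_role_conflict")
  expect_match(tryCatch(signature_of(doc), error = conditionMessage), "X")
})

test_that("signature of a merge equals the union of signatures", {
  for (seed in 1:5) {
    f1 <- random_fixture(seed)$doc
    f2 <- random_fixture(seed + 50)$doc
    m <- merge_documents(list(f1, f2))
    s1 <- signature_of(f1); s2 <- signature_of(f2); sm <- signature_of(m)
    for (slot in names(sm)) {
      expect_setequal(sm[[slot]], union(s1[[slot]], s2[[slot]]))
    }
  }
})
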