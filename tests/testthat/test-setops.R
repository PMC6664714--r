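# merge / select / remove / filter / annotate / diff.

test_that("merge is axiom-set union keeping the first input's identity", {
  x <- random_fixture(1)$doc
  expect_identical(axiom_keys(merge_documents(list(x))), axiom_keys(x))
  y <- ontology_document(ontology_iri = ex("other.owl"), axioms = list(
    ax_subclass(ex("zzz1"), ex("zzz2"))))
  m <- merge_documents(list(x, y))
  expect_identical(sort(union(names(x$axioms), names(y$axioms))),
                   axiom_keys(m))
  expect_identical(m$ontology_iri, x$ontology_iri)
  # associativity
  z <- ontology_document(axioms = list(ax_subclass(ex("q1"), ex("q2"))))
  m1 <- merge_documents(list(merge_documents(list(x, y)), z))
  m2 <- merge_documents(list(x, y, z))
  expect_identical(axiom_keys(m1), axiom_keys(m2))
})

test_that("merge collapses the import closure through the catalog", {
  dir <- withr::local_tempdir()
  imported <- ontology_document(ontology_iri = ex("imp.owl"),
    axioms = list(ax_declaration(ex("I"), "class")))
  write_document(imported, file.path(dir, "imp.ttl"))
  main <- ontology_document(ontology_iri = ex("main.owl"),
    imports = ex("imp.owl"),
    axioms = list(ax_declaration(ex("M"), "class")))
  cat_obj <- catalog(ex("imp.owl"), file.path(dir, "imp.ttl"))
  collapsed <- merge_documents(list(main), collapse_import_closure = TRUE,
                               catalog = cat_obj)
  expect_true("decl(<http://example.org/I>,class)" %in% logical_keys(collapsed))
  expect_length(collapsed$imports, 0)
  kept <- merge_documents(list(main), collapse_import_closure = FALSE)
  expect_identical(kept$imports, ex("imp.owl"))
  expect_false("decl(<http://example.org/I>,class)" %in% logical_keys(kept))
  expect_error(
    merge_documents(list(main), collapse_import_closure = TRUE,
                    catalog = catalog()),
    class = "owlet_unresolved_import")
})

test_that("selectors map entity sets left to right", {
  doc <- ontology_document(axioms = c(
    list(ax_subclass(ex("A"), ex("B")), ax_subclass(ex("B"), ex("C"))),
    lapply(1:10, function(i) ax_declaration(ex(paste0("S", i)), "class")),
    lapply(1:4, function(i) {
      ax_annotation(ex(paste0("S", i)), obo_properties()$subset,
                    literal(sprintf("ChEBI_%d", i)))
    }),
    list(ax_annotation(ex("S9"), obo_properties()$subset,
                       literal("other_subset")))))
  expect_identical(select_entities(doc, ex("A"), list(sel_self())), ex("A"))
  expect_setequal(select_entities(doc, ex("A"), list(sel_ancestors())),
                  c(ex("B"), ex("C")))
  expect_setequal(select_entities(doc, ex("C"), list(sel_descendants())),
                  c(ex("A"), ex("B")))
  hits <- select_entities(doc, character(0),
    list(sel_annotation(obo_properties()$subset, "ChEBI_.*",
                        is_regex = TRUE)))
  expect_setequal(hits, ex(paste0("S", 1:4)))
  expect_error(sel_annotation(obo_properties()$subset, "([", is_regex = TRUE),
               class = "owlet_pattern_error")
})

test_that("remove drops anything touching the set; filter keeps what is about it", {
  doc <- doc_from_edges("A>B", "B>C")
  expect_identical(axiom_keys(remove_axioms(doc, character(0))),
                   axiom_keys(doc))
  removed <- remove_axioms(doc, ex("A"))
  expect_identical(logical_keys(removed), subclass_key("B", "C"))
  filtered <- filter_axioms(doc, ex("B"), types = "subclass")
  expect_identical(logical_keys(filtered), character(0))
  filtered2 <- filter_axioms(doc, c(ex("B"), ex("C")), types = "subclass")
  expect_identical(logical_keys(filtered2), subclass_key("B", "C"))
  # full signature + all types preserves logical content
  full <- filter_axioms(doc, c(ex("A"), ex("B"), ex("C")))
  expect_identical(logical_keys(full), logical_keys(doc))
  expect_length(filter_axioms(doc, character(0))$axioms, 0)
})

test_that("remove and filter never select the same axiom", {
  for (seed in c(4, 9)) {
    fx <- random_fixture(seed)
    cls <- fx$ledger$classes
    ents <- cls[seq(1, length(cls), by = 3)]
    for (types in list("all", "subclass", c("logical", "annotation"))) {
      a <- remove_axioms(fx$doc, ents, types)
      b <- filter_axioms(fx$doc, ents, types)
      expect_length(intersect(names(a$axioms), names(b$axioms)), 0)
      # axioms entirely inside the set are kept by filter, dropped by remove
      # axioms entirely outside survive remove and are dropped by filter
      expect_true(all(names(b$axioms) %in% names(fx$doc$axioms)))
    }
  }
})

test_that("declaration removal only happens for otherwise-unreferenced entities", {
  doc <- ontology_document(axioms = list(
    ax_declaration(ex("A"), "class"), ax_declaration(ex("B"), "class"),
    ax_subclass(ex("B"), ex("A"))))
  # A is referenced by the (unremoved) subclass axiom when only
  # declarations are targeted
  out <- remove_axioms(doc, ex("A"), types = "declaration")
  expect_true("decl(<http://example.org/A>,class)" %in% logical_keys(out))
  out2 <- remove_axioms(doc, ex("A"), types = "all")
  expect_false("decl(<http://example.org/A>,class)" %in% logical_keys(out2))
})

test_that("annotate sets the version IRI and header annotations idempotently", {
  doc <- random_fixture(2)$doc
  v <- ex("fixture/2026-02-02/fixture.owl")
  out <- annotate_document(doc,
    annotations = list(annotation_pair(paste0(NS_DCT, "creator"),
                                       literal("release bot"))),
    version_iri = v)
  expect_identical(out$version_iri, v)
  out2 <- annotate_document(out,
    annotations = list(annotation_pair(paste0(NS_DCT, "creator"),
                                       literal("release bot"))),
    version_iri = v)
  expect_identical(write_document_text(out, "turtle"),
                   write_document_text(out2, "turtle"))
  expect_identical(axiom_keys(out), axiom_keys(doc))
  expect_error(annotate_document(doc, version_iri = "not an iri"),
               class = "owlet_usage_error")
})

test_that("diff is empty on identity and antisymmetric under swap", {
  x <- random_fixture(3)$doc
  d0 <- diff_documents(x, x)
  expect_length(d0$only_in_left, 0)
  expect_length(d0$only_in_right, 0)
  extra <- ax_subclass(ex("new1"), ex("new2"))
  y <- doc_add_axioms(x, list(extra))
  d1 <- diff_documents(x, y)
  expect_identical(d1$only_in_right, axiom_key(extra))
  expect_length(d1$only_in_left, 0)
  d2 <- diff_documents(y, x)
  expect_identical(d2$only_in_left, d1$only_in_right)
  expect_identical(d2$only_in_right, d1$only_in_left)
})
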