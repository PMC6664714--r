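# Module extraction: MIREOT and locality-based BOT/TOP/STAR.

test_that("MIREOT climbs from bottom terms to top terms or the root", {
  chain <- ontology_document(axioms = list(
    ax_declaration(ex("A"), "class"), ax_declaration(ex("B"), "class"),
    ax_declaration(ex("C"), "class"),
    ax_annotation(ex("A"), iri_label, literal("a")),
    ax_subclass(ex("A"), ex("B")), ax_subclass(ex("B"), ex("C"))))
  expect_setequal(signature_of(extract_mireot(chain, ex("A")))$classes,
                  c(ex("A"), ex("B"), ex("C")))
  m2 <- extract_mireot(chain, ex("A"), top_terms = ex("B"))
  expect_setequal(signature_of(m2)$classes, c(ex("A"), ex("B")))
  expect_false(subclass_key("B", "C") %in% logical_keys(m2))
  expect_setequal(signature_of(extract_mireot(chain, ex("C")))$classes,
                  ex("C"))
  # minimal information: labels copied, only is_a edges retained
  expect_true(any(vapply(extract_mireot(chain, ex("A"))$axioms,
                         function(ax) ax$type == "annotation", logical(1))))
  expect_error(extract_mireot(chain, ex("ZZZ")),
               class = "owlet_unknown_term")
})

test_that("MIREOT matches the independent reachability oracle on fixtures", {
  for (seed in c(1, 5, 13, 28)) {
    fx <- generate_fixture(fixture_spec(n_classes = 14, n_properties = 2,
                                        p_existential = 0.3, seed = seed))
    mod <- extract_mireot(fx$doc, fx$ledger$mireot$bottom)
    expect_identical(sort(signature_of(mod)$classes),
                     fx$ledger$mireot$expected_classes,
                     info = sprintf("seed %d", seed))
  }
})

test_that("bottom-locality keeps ancestors, top-locality keeps descendants", {
  doc <- doc_from_edges("A>B", "B>C")
  bot <- extract_slme(doc, ex("B"), "bot")
  expect_identical(setdiff(logical_keys(bot), character(0)),
                   subclass_key("B", "C"))
  top <- extract_slme(doc, ex("B"), "top")
  expect_identical(logical_keys(top), subclass_key("A", "B"))
  # seed covering the whole signature keeps every logical axiom
  full <- extract_slme(doc, c(ex("A"), ex("B"), ex("C")), "bot")
  expect_identical(logical_keys(full),
                   c(subclass_key("A", "B"), subclass_key("B", "C")))
  expect_error(extract_slme(doc, character(0), "bot"),
               class = "owlet_unknown_term")
  expect_error(extract_slme(doc, ex("nope"), "star"),
               class = "owlet_unknown_term")
})

test_that("modules are syntactic sub-modules and STAR is smallest", {
  for (seed in c(2, 7, 16, 31)) {
    fx <- random_fixture(seed, n = 10)
    doc <- fx$doc
    seed_term <- fx$ledger$designated_seed
    mods <- lapply(c(bot = "bot", top = "top", star = "star"),
                   function(m) extract_slme(doc, seed_term, m))
    for (m in mods) {
      expect_true(all(names(m$axioms) %in% names(doc$axioms)),
                  info = sprintf("seed %d", seed))
    }
    star_logical <- logical_keys(mods$star)
    expect_true(all(star_logical %in% logical_keys(mods$bot)),
                info = sprintf("seed %d star vs bot", seed))
    expect_true(all(star_logical %in% logical_keys(mods$top)),
                info = sprintf("seed %d star vs top", seed))
    expect_lte(length(mods$star$axioms), length(mods$bot$axioms))
    expect_lte(length(mods$star$axioms), length(mods$top$axioms))
  }
})

test_that("BOT modules preserve all seed-signature subsumptions", {
  for (seed in c(3, 11, 24)) {
    fx <- random_fixture(seed, n = 10)
    doc <- fx$doc
    cls <- sort(fx$ledger$classes)
    seed_terms <- cls[c(2, length(cls) - 1)]
    mod <- extract_slme(doc, seed_terms, "bot")
    full <- naive_entailed_subsumptions(doc)$subsumptions
    part <- naive_entailed_subsumptions(mod)$subsumptions
    for (x in seed_terms) for (y in seed_terms) {
      if (x == y) next
      before <- any(full$sub == x & full$sup == y)
      after <- any(part$sub == x & part$sup == y)
      expect_identical(after, before,
                       info = sprintf("seed %d: %s < %s", seed, x, y))
    }
  }
})

test_that("source annotation adds one provenance triple per term, idempotently", {
  chain <- ontology_document(axioms = list(
    ax_declaration(ex("A"), "class"), ax_declaration(ex("B"), "class"),
    ax_declaration(ex("C"), "class"),
    ax_subclass(ex("A"), ex("B")), ax_subclass(ex("B"), ex("C"))))
  mod <- extract_mireot(chain, ex("A"))
  ann <- annotate_sources(mod, ex("src.owl"))
  src_anns <- Filter(function(ax) {
    ax$type == "annotation" && ax$property == obo_properties()$source
  }, ann$axioms)
  expect_length(src_anns, 3)
  expect_identical(axiom_keys(annotate_sources(ann, ex("src.owl"))),
                   axiom_keys(ann))
  empty <- ontology_document()
  expect_identical(axiom_keys(annotate_sources(empty, ex("src.owl"))),
                   axiom_keys(empty))
  expect_error(annotate_sources(mod, ""), class = "owlet_usage_error")
  # extract_module dispatch wires the source annotation through
  m <- extract_module(chain, "mireot", bottom_terms = ex("A"),
                      annotate_with_source = TRUE, source_iri = ex("src.owl"))
  expect_true(any(vapply(m$axioms, function(ax) {
    ax$type == "annotation" && identical(ax$value, ex("src.owl"))
  }, logical(1))))
})
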