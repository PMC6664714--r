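# Saturation reasoner: classification, coherence checking, entailment.

test_that("chains classify with transitively reduced direct edges", {
  tax <- classify(doc_from_edges("A>B", "B>C"))
  expect_identical(subsumption_set(tax$direct_edges),
                   c(paste(ex("A"), "<", ex("B")),
                     paste(ex("B"), "<", ex("C"))))
  expect_true(paste(ex("A"), "<", ex("C")) %in%
                subsumption_set(tax$subsumptions))
  expect_length(tax$unsatisfiable, 0)
  expect_true(tax$consistent)
})

test_that("definitions let members classify under defined classes", {
  # A == (B and R some C); D [= B, D [= R some C  =>  D [= A
  doc <- ontology_document(axioms = list(
    ax_equivalent(list(ce_named(ex("A")),
      ce_and(list(ce_named(ex("B")), ce_some(ex("R"), ex("C")))))),
    ax_subclass(ex("D"), ex("B")),
    ax_subclass(ce_named(ex("D")), ce_some(ex("R"), ex("C")))))
  # independent oracle confirms the expected entailment on this instance
  oracle <- naive_entailed_subsumptions(doc)
  expect_true(paste(ex("D"), "<", ex("A")) %in%
                subsumption_set(oracle$subsumptions))
  tax <- classify(doc)
  expect_identical(subsumption_set(tax$subsumptions),
                   subsumption_set(oracle$subsumptions))
})

test_that("disjointness clashes mark classes unsatisfiable", {
  doc <- doc_from_edges("A>B", "A>C",
                        extra = list(ax_disjoint(c(ex("B"), ex("C")))))
  tax <- classify(doc)
  expect_identical(tax$unsatisfiable, ex("A"))
})

test_that("reason asserts inferred direct superclasses and is idempotent", {
  doc <- ontology_document(axioms = list(
    ax_equivalent(list(ce_named(ex("A")), ce_some(ex("R"), ex("B")))),
    ax_subclass(ce_named(ex("C")), ce_some(ex("R"), ex("B")))))
  out <- reason(doc)
  expect_true(subclass_key("C", "A") %in% logical_keys(out))
  # already-classified input passes through unchanged
  expect_identical(axiom_keys(reason(out)), axiom_keys(out))
  # every added axiom is entailed by the input (soundness)
  added_keys <- setdiff(names(out$axioms), names(doc$axioms))
  for (k in added_keys) {
    ax <- out$axioms[[k]]
    expect_true(is_entailed(doc, ax_subclass(ax$sub, ax$sup)))
  }
})

test_that("reason halts on incoherent input, naming the classes", {
  doc <- doc_from_edges("A>B", "A>C",
                        extra = list(ax_disjoint(c(ex("B"), ex("C")))))
  err <- tryCatch(reason(doc), error = function(e) e)
  expect_s3_class(err, "owlet_incoherent")
  expect_match(conditionMessage(err), ex("A"), fixed = TRUE)
})

test_that("equivalent-pair detection can be escalated to an error", {
  doc <- doc_from_edges("A>B", "B>A")
  expect_silent(reason(doc))
  err <- tryCatch(reason(doc, fail_on_equivalent_pairs = TRUE),
                  error = function(e) e)
  expect_s3_class(err, "owlet_equivalent_pair")
  expect_match(conditionMessage(err), ex("A"), fixed = TRUE)
  expect_match(conditionMessage(err), ex("B"), fixed = TRUE)
})

test_that("is_entailed decides reflexivity, transitivity, existential monotonicity", {
  d1 <- doc_from_edges("A>B", "B>C")
  expect_true(is_entailed(d1, ax_subclass(ex("A"), ex("A"))))
  expect_true(is_entailed(d1, ax_subclass(ex("A"), ex("C"))))
  expect_false(is_entailed(d1, ax_subclass(ex("C"), ex("A"))))
  d2 <- ontology_document(axioms = list(
    ax_subclass(ce_named(ex("A")), ce_some(ex("R"), ex("B"))),
    ax_subclass(ex("B"), ex("C"))))
  q <- ax_subclass(ce_named(ex("A")), ce_some(ex("R"), ex("C")))
  expect_true(oracle_entailed(d2, q$sub, q$sup))
  expect_true(is_entailed(d2, q))
  expect_error(is_entailed(d1, ax_declaration(ex("A"), "class")),
               class = "owlet_usage_error")
})

test_that("classification agrees exactly with the exhaustive-closure oracle", {
  for (seed in 1:40) {
    fx <- random_fixture(seed)
    tax <- classify(fx$doc)
    oracle <- fx$ledger
    expect_identical(subsumption_set(tax$subsumptions),
                     subsumption_set(oracle$subsumptions),
                     info = sprintf("seed %d", seed))
    expect_identical(tax$unsatisfiable, oracle$unsatisfiable,
                     info = sprintf("seed %d", seed))
    expect_identical(subsumption_set(tax$direct_edges),
                     subsumption_set(oracle$inferred_direct_edges),
                     info = sprintf("seed %d", seed))
  }
})

test_that("adding axioms never removes entailed subsumptions (monotonicity)", {
  for (seed in c(2, 9, 17)) {
    fx <- random_fixture(seed)
    base <- fx$doc
    before <- subsumption_set(classify(base)$subsumptions)
    cls <- sort(fx$ledger$classes)
    extra <- ax_subclass(cls[length(cls)], cls[2])
    after <- subsumption_set(classify(doc_add_axioms(base, list(extra)))$subsumptions)
    expect_true(all(before %in% after), info = sprintf("seed %d", seed))
  }
})
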