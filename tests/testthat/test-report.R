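# QC report: default battery, profiles, fail-on logic, output formats,
# repair.

test_that("the default profile has three levels, ERROR fail-on and doc links", {
  p <- default_profile()
  expect_identical(p$fail_on, "ERROR")
  levels <- vapply(p$checks, `[[`, character(1), "level")
  expect_setequal(unique(levels), c("ERROR", "WARN", "INFO"))
  expect_true(all(nzchar(vapply(p$checks, `[[`, character(1), "doc_url"))))
  expect_true(all(c("missing_label", "duplicate_label", "equivalent_class_pair",
                    "self_reference", "trailing_whitespace",
                    "invalid_xref_syntax", "definition_format",
                    "missing_definition") %in% names(p$checks)))
})

test_that("clean fixtures report no violations; dirty ones fail on ERROR", {
  clean <- generate_fixture(fixture_spec(n_classes = 8, seed = 41))
  rep <- run_report(clean$doc)
  expect_identical(nrow(rep$violations), 0L)
  expect_false(rep$failed)
  dirty <- generate_fixture(fixture_spec(n_classes = 8, seed = 41,
    violation_census = list(missing_label = 1)))
  rep2 <- run_report(dirty$doc)
  expect_true(any(rep2$violations$rule == "missing_label" &
                    rep2$violations$level == "ERROR"))
  expect_true(rep2$failed)
  # same violations, fail_on none -> no failure
  p <- default_profile(); p$fail_on <- "none"
  rep3 <- run_report(dirty$doc, p)
  expect_identical(rep3$violations, rep2$violations)
  expect_false(rep3$failed)
})

test_that("fail-on is monotone across ERROR/WARN/INFO/none", {
  fx <- generate_fixture(fixture_spec(n_classes = 10, seed = 43,
    violation_census = list(missing_label = 1)))
  failed <- vapply(c("ERROR", "WARN", "INFO", "none"), function(fo) {
    p <- default_profile(); p$fail_on <- fo
    run_report(fx$doc, p)$failed
  }, logical(1))
  expect_identical(unname(failed), c(TRUE, TRUE, TRUE, FALSE))
  # WARN-only violations do not fail at ERROR but do at WARN/INFO
  fx2 <- generate_fixture(fixture_spec(n_classes = 10, seed = 44,
    violation_census = list(self_reference = 1)))
  failed2 <- vapply(c("ERROR", "WARN", "INFO"), function(fo) {
    p <- default_profile(); p$fail_on <- fo
    run_report(fx2$doc, p)$failed
  }, logical(1))
  expect_identical(unname(failed2), c(FALSE, TRUE, TRUE))
})

test_that("injected violation censuses are recovered exactly", {
  censuses <- list(
    list(missing_label = 2, self_reference = 1),
    list(duplicate_label = 3, trailing_whitespace = 2,
         missing_ontology_license = 1),
    list(duplicate_definition = 2, multiple_definitions = 2,
         invalid_xref_syntax = 1, definition_format = 1,
         missing_definition = 1, equivalent_class_pair = 2))
  for (i in seq_along(censuses)) {
    fx <- generate_fixture(fixture_spec(n_classes = 20, seed = 50 + i,
                                        violation_census = censuses[[i]]))
    rep <- run_report(fx$doc)
    got <- table(rep$violations$rule)
    for (rule in names(censuses[[i]])) {
      expect_identical(
        if (rule %in% names(got)) as.integer(got[[rule]]) else 0L,
        as.integer(censuses[[i]][[rule]]),
        info = sprintf("census %d rule %s", i, rule))
    }
    expect_identical(nrow(rep$violations),
                     as.integer(sum(unlist(censuses[[i]]))),
                     info = sprintf("census %d total", i))
  }
})

test_that("reports are deterministic and serialize to tsv/csv/yaml", {
  fx <- generate_fixture(fixture_spec(n_classes = 12, seed = 55,
    violation_census = list(missing_label = 1, self_reference = 1,
                            missing_definition = 1)))
  r1 <- run_report(fx$doc); r2 <- run_report(fx$doc)
  expect_identical(r1$violations, r2$violations)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(r1, tsv, "tsv")
  lines <- readLines(tsv)
  expect_identical(lines[1], "level\trule\tsubject\tproperty\tvalue")
  expect_length(lines, nrow(r1$violations) + 1L)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_report(r1, yml, "yaml")
  back <- yaml::read_yaml(yml)
  expect_length(back, nrow(r1$violations))
  expect_identical(
    vapply(back, `[[`, character(1), "rule"), r1$violations$rule)
  expect_identical(
    vapply(back, `[[`, character(1), "subject"), r1$violations$subject)
  # empty report still writes a header-only table
  empty <- run_report(generate_fixture(fixture_spec(n_classes = 6,
                                                    seed = 77))$doc)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(empty, tsv2, "tsv")
  expect_length(readLines(tsv2), 1)
})

test_that("profiles can override levels, exclude checks and add custom ones", {
  dir <- withr::local_tempdir()
  custom_q <- file.path(dir, "all_classes.rq")
  writeLines(paste0(
    "PREFIX owl: <", NS_OWL, ">\n",
    "SELECT ?subject ?property ?value WHERE { ?subject a owl:Class . ",
    "FILTER(isIRI(?subject)) BIND(\"x\" AS ?property) BIND(\"y\" AS ?value) }"),
    custom_q)
  prof_file <- file.path(dir, "profile.txt")
  writeLines(c("# custom profile",
               "WARN\tmissing_label",
               "exclude\tmissing_definition",
               paste0("INFO\tevery_class\t", custom_q),
               "fail_on\tWARN"), prof_file)
  p <- read_profile(prof_file)
  expect_identical(p$checks$missing_label$level, "WARN")
  expect_null(p$checks$missing_definition)
  expect_identical(p$checks$every_class$level, "INFO")
  expect_identical(p$fail_on, "WARN")
  fx <- generate_fixture(fixture_spec(n_classes = 6, seed = 61,
    violation_census = list(missing_label = 1)))
  rep <- run_report(fx$doc, p)
  expect_identical(
    unname(table(rep$violations$rule)[["every_class"]]), 6L)
  expect_identical(rep$violations$level[rep$violations$rule == "missing_label"],
                   "WARN")
  expect_true(rep$failed)
  # malformed custom query -> profile error naming the check
  writeLines("SELECT oops {", custom_q)
  p2 <- read_profile(prof_file)
  expect_error(run_report(fx$doc, p2), class = "owlet_profile_error")
})

test_that("repair merges duplicate-axiom annotations and rewrites deprecations", {
  p <- obo_properties()
  doc <- ontology_document(axioms = list(
    ax_subclass(ex("A"), ex("B"),
                anns = list(annotation_pair(iri_label, literal("v")))),
    ax_subclass(ex("A"), ex("B"),
                anns = list(annotation_pair(iri_label, literal("w")))),
    ax_subclass(ex("C"), ex("D")),
    ax_annotation(ex("D"), p$deprecated,
                  literal("true", datatype = XSD_BOOLEAN)),
    ax_annotation(ex("D"), p$replaced_by, ex("D2"))))
  out <- repair_document(doc)
  keys <- axiom_keys(out)
  merged <- keys[startsWith(keys, sprintf("sub(<%s>,<%s>)", ex("A"), ex("B")))]
  expect_length(merged, 1)
  expect_match(merged, "\"v\"")
  expect_match(merged, "\"w\"")
  expect_true(subclass_key("C", "D2") %in% logical_keys(out))
  expect_false(subclass_key("C", "D") %in% logical_keys(out))
  # annotations on the deprecated term survive
  expect_true(any(vapply(out$axioms, function(ax) {
    ax$type == "annotation" && ax$subject == ex("D")
  }, logical(1))))
})

test_that("replacement chains resolve transitively; cycles are errors", {
  p <- obo_properties()
  chain <- ontology_document(axioms = list(
    ax_subclass(ex("C"), ex("D")),
    ax_annotation(ex("D"), p$deprecated,
                  literal("true", datatype = XSD_BOOLEAN)),
    ax_annotation(ex("D"), p$replaced_by, ex("Dp")),
    ax_annotation(ex("Dp"), p$deprecated,
                  literal("true", datatype = XSD_BOOLEAN)),
    ax_annotation(ex("Dp"), p$replaced_by, ex("Dpp"))))
  out <- repair_document(chain)
  expect_true(subclass_key("C", "Dpp") %in% logical_keys(out))
  cyc <- ontology_document(axioms = list(
    ax_subclass(ex("C"), ex("D")),
    ax_annotation(ex("D"), p$deprecated,
                  literal("true", datatype = XSD_BOOLEAN)),
    ax_annotation(ex("D"), p$replaced_by, ex("E")),
    ax_annotation(ex("E"), p$deprecated,
                  literal("true", datatype = XSD_BOOLEAN)),
    ax_annotation(ex("E"), p$replaced_by, ex("D"))))
  expect_error(repair_document(cyc), class = "owlet_repair_error")
})

test_that("repair preserves entailments among non-deprecated classes", {
  for (seed in c(6, 15)) {
    fx <- generate_fixture(fixture_spec(n_classes = 10, n_properties = 2,
                                        p_existential = 0.3, seed = seed,
                                        n_deprecated = 2,
                                        n_duplicate_axioms = 1))
    before <- naive_entailed_subsumptions(fx$doc)$subsumptions
    after <- naive_entailed_subsumptions(repair_document(fx$doc))$subsumptions
    depr <- fx$ledger$deprecated_subjects
    keep <- !(before$sub %in% depr) & !(before$sup %in% depr)
    pairs_before <- paste(before$sub[keep], before$sup[keep])
    pairs_after <- paste(after$sub, after$sup)
    expect_true(all(pairs_before %in% pairs_after),
                info = sprintf("seed %d", seed))
  }
})
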