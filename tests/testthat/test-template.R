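# Template-driven term generation.

write_template <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("template parsing validates structure and template strings", {
  good <- write_template(c(
    "Identifier\tName\tParent",
    "ID\tLABEL\tSC %",
    "X:1\talpha\tX:2"))
  tpl <- parse_template(good)
  expect_length(tpl$templates, 3)
  expect_identical(tpl$id_col, 1L)
  bad_string <- write_template(c("a\tb", "ID\tXYZ %", "X:1\tv"))
  expect_error(parse_template(bad_string), class = "owlet_template_error")
  no_id <- write_template(c("a\tb", "LABEL\tSC %", "v\tX:2"))
  expect_error(parse_template(no_id), class = "owlet_template_error")
  ragged <- write_template(c("a\tb", "ID\tLABEL", "X:1\tv\textra"))
  expect_error(parse_template(ragged), class = "owlet_template_error")
})

test_that("rows expand to declarations, labels and subclass axioms", {
  path <- write_template(c(
    "Identifier\tName\tParent\tDefinition\tPart of",
    "ID\tLABEL\tSC %\tA obo:IAO_0000115\tSC EX:partOf some %",
    "EX:1\talpha\tEX:2\tA def.\tEX:3",
    "EX:2\tbeta\t\t\t"))
  doc <- expand_template(parse_template(path),
                         prefixes = c(EX = "http://example.org/"))
  keys <- logical_keys(doc)
  expect_true("decl(<http://example.org/1>,class)" %in% keys)
  expect_true(subclass_key("1", "2") %in% keys)
  expect_true(sprintf("ann(<%s>,<%s>,\"alpha\")", ex("1"), iri_label) %in% keys)
  expect_true(sprintf("ann(<%s>,<%s>,\"A def.\")", ex("1"), iri_definition)
              %in% keys)
  expect_true(sprintf("sub(<%s>,some(<%s>,<%s>))",
                      ex("1"), ex("partOf"), ex("3")) %in% keys)
  # empty SC cell contributes nothing for that row
  expect_false(any(grepl("sub\\(<http://example.org/2>", keys)))
  # one declared entity per data row
  decls <- Filter(function(ax) ax$type == "declaration", doc$axioms)
  expect_length(decls, 2)
})

test_that("expansion is deterministic and row-order independent", {
  rows <- c("EX:1\talpha\tEX:2", "EX:2\tbeta\t", "EX:3\tgamma\tEX:1")
  header <- c("ID col\tname\tparent", "ID\tLABEL\tSC %")
  d1 <- expand_template(parse_template(write_template(c(header, rows))),
                        prefixes = c(EX = "http://example.org/"))
  d2 <- expand_template(parse_template(write_template(c(header, rev(rows)))),
                        prefixes = c(EX = "http://example.org/"))
  expect_identical(axiom_keys(d1), axiom_keys(d2))
  expect_identical(write_document_text(d1, "turtle"),
                   write_document_text(d2, "turtle"))
})

test_that("CSV dialect and EC/TYPE columns work; bad CURIEs are row errors", {
  path <- write_template(c(
    "id,type,equivalent",
    "ID,TYPE,EC EX:hasPart some %",
    "EX:10,class,EX:11",
    "EX:12,object_property,"), ext = ".csv")
  doc <- expand_template(parse_template(path),
                         prefixes = c(EX = "http://example.org/"))
  keys <- logical_keys(doc)
  expect_true("decl(<http://example.org/12>,object_property)" %in% keys)
  expect_true(sprintf("equiv(<%s>,some(<%s>,<%s>))",
                      ex("10"), ex("hasPart"), ex("11")) %in% keys)
  bad <- write_template(c("id\tparent", "ID\tSC %", "NOPREFIX:1\tEX:2"))
  expect_error(expand_template(parse_template(bad),
                               prefixes = c(EX = "http://example.org/")),
               class = "owlet_template_error")
})

test_that("labels queried from the expanded module reconstruct the LABEL column", {
  path <- write_template(c(
    "id\tname",
    "ID\tLABEL",
    "EX:1\talpha", "EX:2\tbeta", "EX:3\tgamma"))
  doc <- expand_template(parse_template(path),
                         prefixes = c(EX = "http://example.org/"))
  tbl <- run_select(doc, paste0(
    "PREFIX rdfs: <", NS_RDFS, ">\n",
    "SELECT ?l WHERE { ?c rdfs:label ?l }"))
  expect_identical(sort(vapply(tbl$rows, `[[`, character(1), "l")),
                   c("alpha", "beta", "gamma"))
})

test_that("template modules merge into an editors' ontology and reason cleanly", {
  fx <- generate_fixture(fixture_spec(n_classes = 8, seed = 71))
  root <- fx$ledger$classes[1]
  path <- write_template(c(
    "id\tname\tparent",
    "ID\tLABEL\tSC %",
    paste0("FX:T1\tnew term one\t<", root, ">")))
  # cell values may be full IRIs in angle brackets or CURIEs
  tpl <- parse_template(path)
  tpl$rows[[1]][3] <- root
  module <- expand_template(tpl, prefixes = c(FX = FX_NS))
  merged <- merge_documents(list(fx$doc, module))
  reasoned <- reason(merged)
  expect_true(sprintf("sub(<%sT1>,<%s>)", FX_NS, root) %in%
                logical_keys(reasoned))
})
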