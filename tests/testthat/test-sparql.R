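# SPARQL query/verify over the document's RDF view.

sparql_prefixes <- paste0(
  "PREFIX owl: <", NS_OWL, ">\n",
  "PREFIX rdfs: <", NS_RDFS, ">\n")

three_class_doc <- function() {
  ontology_document(
    ontology_iri = ex("q.owl"),
    axioms = list(
      ax_declaration(ex("A"), "class"), ax_declaration(ex("B"), "class"),
      ax_declaration(ex("C"), "class"),
      ax_annotation(ex("A"), iri_label, literal("alpha")),
      ax_subclass(ex("A"), ex("B"))))
}

test_that("graph views expose imports as named graphs with a union default", {
  doc <- three_class_doc()
  v0 <- to_graph_view(doc, use_graphs = FALSE)
  expect_length(v0$named_graphs, 0)
  dir <- withr::local_tempdir()
  imp <- ontology_document(ontology_iri = ex("imp.owl"),
    axioms = list(ax_declaration(ex("I"), "class")))
  write_document(imp, file.path(dir, "imp.ttl"))
  doc2 <- three_class_doc()
  doc2$imports <- ex("imp.owl")
  v1 <- to_graph_view(doc2, use_graphs = TRUE,
                      catalog = catalog(ex("imp.owl"),
                                        file.path(dir, "imp.ttl")))
  expect_identical(names(v1$named_graphs), ex("imp.owl"))
  # union property: every named-graph triple appears in the default graph
  key <- function(tr) paste(tr$s, tr$p, tr$o)
  expect_true(all(key(v1$named_graphs[[1]]) %in% key(v1$default_graph)))
})

test_that("select, ask, construct and update follow SPARQL semantics", {
  doc <- three_class_doc()
  tbl <- run_select(doc, paste0(sparql_prefixes,
    "SELECT ?c WHERE { ?c a owl:Class . FILTER(isIRI(?c)) }"))
  expect_length(tbl$rows, 3)
  expect_identical(tbl$header, "c")
  expect_true(run_ask(doc, paste0(sparql_prefixes,
    "ASK { <", ex("A"), "> rdfs:subClassOf <", ex("B"), "> }")))
  expect_false(run_ask(doc, paste0(sparql_prefixes,
    "ASK { <", ex("B"), "> rdfs:subClassOf <", ex("A"), "> }")))
  # update inserting a label becomes an annotation axiom in the model
  upd <- run_update(doc, paste0(sparql_prefixes,
    "INSERT DATA { <", ex("C"), "> rdfs:label \"gamma\" }"))
  expect_true(sprintf("ann(<%s>,<%s>,\"gamma\")", ex("C"), iri_label) %in%
                logical_keys(upd))
  tr <- run_construct(doc, paste0(sparql_prefixes,
    "CONSTRUCT { ?c rdfs:seeAlso <", ex("ref"), "> } WHERE { ?c a owl:Class . FILTER(isIRI(?c)) }"))
  expect_identical(nrow(tr), 3L)
  # a parse error surfaces as a distinct sparql error
  expect_error(run_select(doc, "SELECT WHERE {"),
               class = "owlet_sparql_error")
})

test_that("querying the use-graphs union equals querying the merged document", {
  dir <- withr::local_tempdir()
  imp <- ontology_document(ontology_iri = ex("imp.owl"),
    axioms = list(ax_declaration(ex("I"), "class"),
                  ax_annotation(ex("I"), iri_label, literal("imported"))))
  write_document(imp, file.path(dir, "imp.ttl"))
  main <- three_class_doc()
  main$imports <- ex("imp.owl")
  cat_obj <- catalog(ex("imp.owl"), file.path(dir, "imp.ttl"))
  q <- paste0(sparql_prefixes,
              "SELECT ?c WHERE { ?c a owl:Class . FILTER(isIRI(?c)) }")
  via_graphs <- run_select(to_graph_view(main, TRUE, cat_obj), q)
  merged <- merge_documents(list(main), collapse_import_closure = TRUE,
                            catalog = cat_obj)
  via_merge <- run_select(merged, q)
  expect_identical(via_graphs$rows, via_merge$rows)
})

test_that("verify succeeds on conforming input and dumps violating rows", {
  multi_label <- paste0(sparql_prefixes,
    "SELECT ?c ?l1 ?l2 WHERE { ?c rdfs:label ?l1 , ?l2 . FILTER(?l1 < ?l2) }")
  clean <- three_class_doc()
  outdir <- withr::local_tempdir()
  res <- verify_queries(clean, list(multi_label = multi_label), outdir)
  expect_identical(res$status, 0L)
  expect_length(list.files(outdir), 0)
  # two multi-labeled classes -> non-zero status, 2 data rows in the CSV
  dirty <- doc_add_axioms(clean, list(
    ax_annotation(ex("A"), iri_label, literal("alpha duplicate")),
    ax_annotation(ex("B"), iri_label, literal("beta")),
    ax_annotation(ex("B"), iri_label, literal("beta duplicate"))))
  res2 <- verify_queries(dirty, list(multi_label = multi_label), outdir)
  expect_identical(res2$status, 1L)
  csv <- readLines(file.path(outdir, "multi_label.csv"))
  expect_length(csv, 3)  # header + 2 data rows
  # empty query list is vacuously conforming
  expect_identical(verify_queries(dirty, list())$status, 0L)
  # status is 0 iff total returned rows is 0
  expect_identical(res2$status == 0L, sum(res2$counts) == 0L)
  expect_identical(res$status == 0L, sum(res$counts) == 0L)
})

test_that("CSV and TSV renderings carry identical cell values", {
  doc <- three_class_doc()
  tbl <- run_select(doc, paste0(sparql_prefixes,
    "SELECT ?c ?l WHERE { ?c rdfs:label ?l }"))
  csv <- strsplit(result_table_csv(tbl, ","), "\n")[[1]]
  tsv <- strsplit(result_table_csv(tbl, "\t"), "\n")[[1]]
  expect_identical(gsub(",", "\t", csv), tsv)
})
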