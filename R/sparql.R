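# SPARQL query, ask, construct, update and verify over the document's RDF
# view.  This module owns the document <-> graph mapping, result
# determinism (sorted row rendering) and the exit-code contract; query
# execution itself is delegated to the host RDF stack (Python rdflib)
# through a subprocess bridge, with all graphs exchanged as N-Triples and
# results as SPARQL 1.1 JSON.

python_binary <- function() {
  override <- getOption("owlet.python", Sys.getenv("OWLET_PYTHON", ""))
  if (nzchar(override)) return(override)
  for (cand in c("python3", "python")) {
    if (nzchar(Sys.which(cand))) return(cand)
  }
  owlet_stop("owlet_io_error", "no python interpreter found for SPARQL bridge")
}

bridge_script <- function() {
  path <- system.file("python", "sparql_bridge.py", package = "owlet")
  if (!nzchar(path)) {
    # during development (package not installed) fall back to source tree
    path <- file.path("inst", "python", "sparql_bridge.py")
  }
  path
}

nt_term <- function(value, kind, lang, dt) {
  if (kind == "iri") return(paste0("<", value, ">"))
  if (kind == "bnode") return(paste0("_:", gsub("[^A-Za-z0-9]", "", value)))
  lit <- paste0("\"", escape_turtle_string(value), "\"")
  if (!is.na(lang)) return(paste0(lit, "@", lang))
  if (!is.na(dt)) return(paste0(lit, "^^<", dt, ">"))
  lit
}

triples_to_ntriples <- function(tr) {
  if (!nrow(tr)) return("")
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    paste(nt_term(tr$s[i], tr$s_kind[i], NA, NA),
          nt_term(tr$p[i], "iri", NA, NA),
          nt_term(tr$o[i], tr$o_kind[i], tr$lang[i], tr$dt[i]), ".")
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

# ---- GraphView -------------------------------------------------------------

#' Build the RDF graph view of a document
#'
#' @param doc an ontology document.
#' @param use_graphs expose resolved imports as named graphs (keyed by
#'   each import's ontology IRI); the default graph is then the union of
#'   all graphs.
#' @param catalog an `owlet_catalog`, required when `use_graphs` and the
#'   document declares imports.
#' @return An object of class `owlet_graph_view` with `default_graph`
#'   (triples) and `named_graphs` (list of triples keyed by IRI).
#' @export
to_graph_view <- function(doc, use_graphs = FALSE, catalog = NULL) {
  own <- doc_to_triples(doc)
  named <- list()
  if (use_graphs) {
    imported <- resolve_imports(doc, catalog)
    for (iri in names(imported)) {
      named[[iri]] <- doc_to_triples(imported[[iri]])
    }
  }
  default <- own
  for (g in named) default <- rbind(default, g)
  structure(list(default_graph = default, named_graphs = named),
            class = "owlet_graph_view")
}

run_bridge <- function(view, operations, workdir) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  default_path <- file.path(workdir, "default.nt")
  writeLines(triples_to_ntriples(view$default_graph), default_path, sep = "")
  named <- list()
  i <- 0L
  for (iri in names(view$named_graphs)) {
    i <- i + 1L
    p <- file.path(workdir, sprintf("named%d.nt", i))
    writeLines(triples_to_ntriples(view$named_graphs[[iri]]), p, sep = "")
    named[[iri]] <- p
  }
  manifest <- list(
    default_graph = default_path,
    named_graphs = if (length(named)) named else NULL,
    operations = operations)
  manifest_path <- file.path(workdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null")
  err_path <- file.path(workdir, "stderr.txt")
  status <- suppressWarnings(system2(
    python_binary(), c(bridge_script(), manifest_path),
    stdout = FALSE, stderr = err_path))
  if (status != 0) {
    err <- tryCatch(paste(readLines(err_path, warn = FALSE), collapse = " "),
                    error = function(e) "")
    owlet_stop("owlet_sparql_error",
      sprintf("SPARQL bridge failed (status %d): %s", status, err),
      list(status = status))
  }
  invisible(TRUE)
}

parse_sparql_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

render_binding <- function(b) {
  if (is.null(b)) return("")
  switch(b$type,
    uri = b$value,
    literal = b$value,
    `typed-literal` = b$value,
    bnode = paste0("_:", b$value),
    b$value)
}

# Execute several SELECT queries in one bridge invocation (amortizes the
# interpreter startup across a whole QC battery).
run_select_many <- function(view, queries) {
  view <- as_graph_view(view)
  workdir <- tempfile("owlet_sparql_")
  on.exit(unlink(workdir, recursive = TRUE))
  dir.create(workdir, recursive = TRUE)
  ops <- list()
  for (i in seq_along(queries)) {
    qf <- file.path(workdir, sprintf("query%d.rq", i))
    writeLines(queries[[i]], qf)
    ops[[i]] <- list(id = names(queries)[i] %||% sprintf("q%d", i),
                     type = "select", query_file = qf,
                     out = file.path(workdir, sprintf("result%d.json", i)))
  }
  run_bridge(view, ops, workdir)
  out <- lapply(seq_along(queries), function(i) {
    res <- parse_sparql_json(ops[[i]]$out)
    header <- unlist(res$head$vars)
    if (is.null(header)) header <- character(0)
    rows <- lapply(res$results$bindings, function(binding) {
      vapply(header, function(v) render_binding(binding[[v]]), character(1))
    })
    if (length(rows)) {
      rendering <- vapply(rows, paste, character(1), collapse = "\r")
      rows <- rows[order(rendering)]
    }
    structure(list(header = header, rows = rows),
              class = "owlet_result_table")
  })
  names(out) <- names(queries)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a SPARQL SELECT query
#'
#' @param view an `owlet_graph_view` (or an ontology document, coerced
#'   with default options).
#' @param query SPARQL SELECT text.
#' @return An object of class `owlet_result_table`: list with `header`
#'   (variable names) and `rows` (list of character vectors, sorted by
#'   their rendering for stable output).
#' @export
run_select <- function(view, query) {
  run_select_many(view, list(query))[[1]]
}

as_graph_view <- function(x) {
  if (inherits(x, "owlet_graph_view")) x
  else if (inherits(x, "owlet_document")) to_graph_view(x)
  else owlet_stop("owlet_usage_error", "expected a document or graph view")
}

#' @export
print.owlet_result_table <- function(x, ...) {
  cat("<owlet_result_table>", length(x$rows), "row(s):",
      paste(x$header, collapse = ", "), "\n")
  invisible(x)
}

#' Run a SPARQL ASK query
#' @inheritParams run_select
#' @return Logical scalar.
#' @export
run_ask <- function(view, query) {
  view <- as_graph_view(view)
  workdir <- tempfile("owlet_sparql_")
  on.exit(unlink(workdir, recursive = TRUE))
  dir.create(workdir, recursive = TRUE)
  qf <- file.path(workdir, "query.rq")
  writeLines(query, qf)
  out <- file.path(workdir, "result.json")
  run_bridge(view, list(list(id = "q", type = "ask", query_file = qf,
                             out = out)), workdir)
  isTRUE(parse_sparql_json(out)$boolean)
}

#' Run a SPARQL CONSTRUCT query
#' @inheritParams run_select
#' @return A triple data.frame (mergeable back into a document via
#'   [triples_to_doc()] and [merge_documents()]).
#' @export
run_construct <- function(view, query) {
  view <- as_graph_view(view)
  workdir <- tempfile("owlet_sparql_")
  on.exit(unlink(workdir, recursive = TRUE))
  dir.create(workdir, recursive = TRUE)
  qf <- file.path(workdir, "query.rq")
  writeLines(query, qf)
  out <- file.path(workdir, "result.nt")
  run_bridge(view, list(list(id = "q", type = "construct", query_file = qf,
                             out = out)), workdir)
  text <- paste(readLines(out, warn = FALSE), collapse = "\n")
  parse_turtle(text)$triples
}

#' Run a SPARQL UPDATE against a document
#'
#' The document's RDF view is updated and converted back into the
#' internal model; an update that introduces constructs outside the
#' supported grammar is a conversion error.
#'
#' @param doc an ontology document.
#' @param query SPARQL UPDATE text.
#' @return The updated ontology document.
#' @export
run_update <- function(doc, query) {
  view <- to_graph_view(doc)
  workdir <- tempfile("owlet_sparql_")
  on.exit(unlink(workdir, recursive = TRUE))
  dir.create(workdir, recursive = TRUE)
  qf <- file.path(workdir, "query.rq")
  writeLines(query, qf)
  out <- file.path(workdir, "updated.nt")
  run_bridge(view, list(list(id = "q", type = "update", query_file = qf,
                             out = out)), workdir)
  text <- paste(readLines(out, warn = FALSE), collapse = "\n")
  triples_to_doc(parse_turtle(text)$triples, prefixes = doc$prefixes,
                 source = "sparql update result")
}

# ---- verify ----------------------------------------------------------------

result_table_csv <- function(tbl, sep = ",") {
  quote_cell <- function(x) {
    if (grepl("[\",\n\t]", x)) paste0("\"", gsub("\"", "\"\"", x), "\"") else x
  }
  lines <- paste(vapply(tbl$header, quote_cell, character(1)),
                 collapse = sep)
  for (r in tbl$rows) {
    lines <- c(lines, paste(vapply(r, quote_cell, character(1)),
                            collapse = sep))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Verify an ontology against a set of violation queries
#'
#' Each query is a SPARQL SELECT written so that any returned row is a
#' violation.  Verification succeeds (status 0) iff every query returns
#' zero rows; otherwise status 1 is returned and each offending query's
#' rows are written as CSV into `output_dir`.  A query that fails to
#' parse is a usage error (status 2), with no rows written.
#'
#' @param doc an ontology document (or graph view).
#' @param queries named list or character vector of SPARQL SELECT texts;
#'   names label the report files.
#' @param output_dir directory for violation CSVs (created on demand).
#' @return A list of class `owlet_verify_result`: `status` (0 or 1),
#'   `counts` (named row counts), `files` (written CSV paths).
#' @export
verify_queries <- function(doc, queries, output_dir = NULL) {
  if (!length(queries)) {
    return(structure(list(status = 0L, counts = integer(0),
                          files = character(0)),
                     class = "owlet_verify_result"))
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- sprintf("query_%d", seq_along(queries))
  }
  view <- as_graph_view(doc)
  tbls <- run_select_many(view, as.list(queries))
  counts <- integer(0)
  files <- character(0)
  status <- 0L
  for (nm in names(queries)) {
    tbl <- tbls[[nm]]
    counts[nm] <- length(tbl$rows)
    if (length(tbl$rows)) {
      status <- 1L
      if (!is.null(output_dir)) {
        dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(output_dir, paste0(nm, ".csv"))
        writeLines(result_table_csv(tbl), path, sep = "")
        files <- c(files, path)
      }
    }
  }
  structure(list(status = status, counts = counts, files = files),
            class = "owlet_verify_result")
}

#' @export
print.owlet_verify_result <- function(x, ...) {
  cat("<owlet_verify_result> status:", x$status, "\n")
  if (length(x$counts)) {
    for (nm in names(x$counts)) cat(" ", nm, ":", x$counts[[nm]], "row(s)\n")
  }
  invisible(x)
}
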