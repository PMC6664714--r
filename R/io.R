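# Reading/writing ontology documents and resolving imports via a local
# catalog.  Format is inferred from the file extension (.ttl, .owl, .obo)
# unless given explicitly; content is never sniffed.  There is no network
# retrieval anywhere: import IRIs resolve only through the catalog.

infer_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
    ttl = "turtle",
    owl = "rdfxml",
    rdf = "rdfxml",
    obo = "obo",
    owlet_stop("owlet_usage_error",
      sprintf("cannot infer format from extension of '%s'; pass `format`",
              path)))
}

#' Read an ontology document from a file
#'
#' @param path file path.
#' @param format `"turtle"`, `"rdfxml"` or `"obo"`; inferred from the
#'   extension when `NULL`.
#' @param props annotation-property configuration (OBO only).
#' @return An ontology document.
#' @export
read_document <- function(path, format = NULL, props = obo_properties()) {
  if (!file.exists(path)) {
    owlet_stop("owlet_io_error", sprintf("file not found: %s", path))
  }
  format <- if (is.null(format)) infer_format(path)
            else match.arg(format, c("turtle", "rdfxml", "obo"))
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  read_document_text(text, format, source = path, props = props)
}

#' @rdname read_document
#' @param text document text.
#' @param source label used in error messages.
#' @export
read_document_text <- function(text, format, source = "text",
                               props = obo_properties()) {
  if (format == "obo") return(read_obo_text(text, props))
  parsed <- if (format == "turtle") parse_turtle(text) else parse_rdfxml(text)
  triples_to_doc(parsed$triples, prefixes = parsed$prefixes, source = source)
}

#' Write an ontology document to a file
#'
#' Serialization is byte-deterministic: a pure function of the document,
#' with axioms sorted by (variant rank, canonical rendering) and prefixes
#' sorted by name.  Writing the same document twice produces identical
#' bytes.
#'
#' @param doc an ontology document.
#' @param path output file path.
#' @param format `"turtle"`, `"rdfxml"` or `"obo"`; inferred from the
#'   extension when `NULL`.
#' @param props annotation-property configuration (OBO only).
#' @param lossy OBO only: drop non-expressible axioms instead of erroring.
#' @return `path`, invisibly.
#' @export
write_document <- function(doc, path, format = NULL,
                           props = obo_properties(), lossy = FALSE) {
  format <- if (is.null(format)) infer_format(path)
            else match.arg(format, c("turtle", "rdfxml", "obo"))
  text <- write_document_text(doc, format, props = props, lossy = lossy)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(text), con)
  invisible(path)
}

#' @rdname write_document
#' @export
write_document_text <- function(doc, format, props = obo_properties(),
                                lossy = FALSE) {
  switch(format,
    obo = write_obo_text(doc, props = props, lossy = lossy),
    turtle = triples_to_turtle(doc_to_triples(doc), doc$prefixes),
    rdfxml = triples_to_rdfxml(doc_to_triples(doc), doc$prefixes))
}

# ---- Catalog ---------------------------------------------------------------

#' Read an import catalog
#'
#' Accepts either an OASIS XML catalog (`<uri name="IRI" uri="path"/>`
#' entries) or a simple TSV file (`iri<TAB>path` per line, `#` comments
#' allowed).  Relative paths are resolved against the catalog's directory.
#'
#' @param path catalog file path.
#' @return A named character vector mapping ontology IRI to file path,
#'   of class `owlet_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    owlet_stop("owlet_io_error", sprintf("catalog not found: %s", path))
  }
  dir <- dirname(path)
  entries <- character(0)
  if (tolower(tools::file_ext(path)) == "xml") {
    docx <- xml2::read_xml(path)
    uris <- xml2::xml_find_all(docx, ".//*[local-name()='uri']")
    for (u in uris) {
      entries[xml2::xml_attr(u, "name")] <- xml2::xml_attr(u, "uri")
    }
  } else {
    for (ln in readLines(path, warn = FALSE)) {
      ln <- trimws(ln)
      if (!nzchar(ln) || startsWith(ln, "#")) next
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        owlet_stop("owlet_parse_error",
          sprintf("catalog: expected 'iri<TAB>path', got: %s", ln))
      }
      entries[parts[1]] <- parts[2]
    }
  }
  rel <- !grepl("^(/|[A-Za-z]:)", entries)
  entries[rel] <- file.path(dir, entries[rel])
  structure(entries, class = "owlet_catalog")
}

#' Build a catalog in memory
#' @param iris character vector of ontology IRIs.
#' @param paths parallel character vector of file paths.
#' @return An `owlet_catalog`.
#' @export
catalog <- function(iris = character(0), paths = character(0)) {
  structure(stats::setNames(paths, iris), class = "owlet_catalog")
}

catalog_lookup <- function(cat, iri) {
  if (is.null(cat) || !(iri %in% names(cat))) {
    owlet_stop("owlet_unresolved_import",
      sprintf("import <%s> is not mapped in the catalog (no network fetch)",
              iri), list(iri = iri))
  }
  path <- cat[[iri]]
  if (!file.exists(path)) {
    owlet_stop("owlet_unresolved_import",
      sprintf("import <%s> maps to missing file: %s", iri, path))
  }
  path
}

#' Resolve the import closure of a document
#'
#' Depth-first in declaration order, each IRI loaded exactly once; cycles
#' are permitted and broken on revisit.
#'
#' @param doc an ontology document.
#' @param catalog an `owlet_catalog` mapping IRIs to local files.
#' @return List of ontology documents (the closure, excluding `doc`),
#'   named by IRI.
#' @export
resolve_imports <- function(doc, catalog = NULL) {
  visited <- character(0)
  out <- list()
  visit <- function(d) {
    for (iri in d$imports) {
      if (iri %in% visited) next
      visited <<- c(visited, iri)
      imported <- read_document(catalog_lookup(catalog, iri))
      out[[iri]] <<- imported
      visit(imported)
    }
  }
  visit(doc)
  out
}
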