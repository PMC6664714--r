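# Spreadsheet-template term generation: a TSV/CSV table whose first row
# holds human-readable column labels (ignored), second row holds template
# strings, and rows 3+ hold term data.  Supported template strings:
#   ID            entity identifier (CURIE or IRI); exactly one column
#   LABEL         rdfs:label annotation
#   TYPE          entity type (class by default; object_property, ...)
#   A <property>  annotation with the given property CURIE/IRI
#   SC %          named superclass from the cell value
#   SC <expr> %   superclass expression with the cell substituted at %,
#                 where <expr> is of the form "R some %"
#   EC %          equivalent class (same % patterns as SC)
# Anything else is rejected loudly; cell values for SC/EC columns are
# CURIEs/IRIs, never labels.

parse_csv_line <- function(line, sep) {
  out <- character(0)
  field <- character(0)
  in_quote <- FALSE
  chars <- strsplit(line, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "\"") {
        if (i < length(chars) && chars[i + 1L] == "\"") {
          field <- c(field, "\""); i <- i + 2L; next
        }
        in_quote <- FALSE; i <- i + 1L; next
      }
      field <- c(field, ch); i <- i + 1L; next
    }
    if (ch == "\"" && !length(field)) { in_quote <- TRUE; i <- i + 1L; next }
    if (ch == sep) {
      out <- c(out, paste(field, collapse = "")); field <- character(0)
      i <- i + 1L; next
    }
    field <- c(field, ch); i <- i + 1L
  }
  c(out, paste(field, collapse = ""))
}

TEMPLATE_RE <- list(
  id = "^ID$",
  label = "^LABEL$",
  type = "^TYPE$",
  annotation = "^A +(\\S+)$",
  sc_named = "^SC %$",
  sc_expr = "^SC +(\\S+) +some +% *$",
  ec_named = "^EC %$",
  ec_expr = "^EC +(\\S+) +some +% *$"
)

classify_template_string <- function(s) {
  s <- trimws(s)
  for (kind in names(TEMPLATE_RE)) {
    m <- regmatches(s, regexec(TEMPLATE_RE[[kind]], s))[[1]]
    if (length(m)) {
      return(list(kind = kind,
                  property = if (length(m) > 1) m[2] else NULL))
    }
  }
  owlet_stop("owlet_template_error",
    sprintf("unknown template string: '%s'", s))
}

#' Parse a template table
#'
#' @param path TSV or CSV file path.
#' @param dialect `"tsv"` or `"csv"`; inferred from the extension when
#'   `NULL`.
#' @return An object of class `owlet_template`: `headers`, `templates`
#'   (parsed column roles), `rows` (list of character vectors), `id_col`.
#' @export
parse_template <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)), csv = "csv", "tsv")
  }
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    owlet_stop("owlet_template_error",
      "template needs a header row and a template-string row")
  }
  cells <- lapply(lines, parse_csv_line, sep = sep)
  arity <- length(cells[[1]])
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != arity) {
      owlet_stop("owlet_template_error",
        sprintf("row %d has %d column(s), expected %d",
                i, length(cells[[i]]), arity))
    }
  }
  templates <- lapply(seq_len(arity), function(j) {
    tryCatch(classify_template_string(cells[[2]][j]),
      owlet_template_error = function(e) {
        owlet_stop("owlet_template_error",
          sprintf("column %d: %s", j, conditionMessage(e)))
      })
  })
  id_cols <- which(vapply(templates, function(t) t$kind == "id", logical(1)))
  if (length(id_cols) != 1) {
    owlet_stop("owlet_template_error",
      sprintf("template must have exactly one ID column, found %d",
              length(id_cols)))
  }
  structure(list(
    headers = cells[[1]],
    templates = templates,
    rows = if (length(cells) > 2) cells[3:length(cells)] else list(),
    id_col = id_cols
  ), class = "owlet_template")
}

#' Expand a template table into an ontology module
#'
#' Each data row yields a declaration (type from the TYPE column,
#' defaulting to class), a label annotation from LABEL, and one
#' axiom/annotation per nonempty templated cell.  Empty cells contribute
#' nothing.  The result is a standalone module document.
#'
#' @param template an `owlet_template` from [parse_template()].
#' @param prefixes named character vector used to expand CURIE cells.
#' @param props annotation-property configuration (label property).
#' @return An ontology document.
#' @export
expand_template <- function(template, prefixes = character(0),
                            props = obo_properties()) {
  pfx <- default_prefixes()
  if (length(prefixes)) pfx[names(prefixes)] <- unname(prefixes)
  # a cell must expand to an absolute IRI; an unexpanded CURIE (unknown
  # prefix) is a row-addressed error, not a silently minted IRI
  expand_cell <- function(v, rownum) {
    iri <- expand_curie(v, pfx)
    absolute <- grepl("^[A-Za-z][A-Za-z0-9+.-]*://", iri) ||
      grepl("^(urn|mailto):", iri)
    if (!absolute || grepl("\\s", iri)) {
      owlet_stop("owlet_template_error",
        sprintf("row %d: cannot expand '%s' to an IRI", rownum, v))
    }
    iri
  }
  axioms <- list()
  add <- function(ax) axioms[[length(axioms) + 1L]] <<- ax
  for (k in seq_along(template$rows)) {
    row <- template$rows[[k]]
    rownum <- k + 2L
    id_val <- trimws(row[[template$id_col]])
    if (!nzchar(id_val)) {
      owlet_stop("owlet_template_error",
        sprintf("row %d: empty ID cell", rownum))
    }
    iri <- expand_cell(id_val, rownum)
    # declaration: TYPE column if present and nonempty, else class
    etype <- "class"
    for (j in seq_along(template$templates)) {
      if (template$templates[[j]]$kind == "type" && nzchar(trimws(row[[j]]))) {
        etype <- match.arg(trimws(row[[j]]),
          c("class", "object_property", "annotation_property", "individual"))
      }
    }
    add(ax_declaration(iri, etype))
    for (j in seq_along(template$templates)) {
      t <- template$templates[[j]]
      v <- trimws(row[[j]])
      if (t$kind %in% c("id", "type") || !nzchar(v)) next
      switch(t$kind,
        label = add(ax_annotation(iri, props$label, literal(v))),
        annotation = add(ax_annotation(iri, expand_cell(t$property, rownum),
                                       literal(v))),
        sc_named = add(ax_subclass(ce_named(iri),
                                   ce_named(expand_cell(v, rownum)))),
        sc_expr = add(ax_subclass(ce_named(iri),
          ce_some(expand_cell(t$property, rownum),
                  ce_named(expand_cell(v, rownum))))),
        ec_named = add(ax_equivalent(list(ce_named(iri),
                                          ce_named(expand_cell(v, rownum))))),
        ec_expr = add(ax_equivalent(list(ce_named(iri),
          ce_some(expand_cell(t$property, rownum),
                  ce_named(expand_cell(v, rownum)))))))
    }
  }
  ontology_document(prefixes = prefixes, axioms = axioms)
}
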