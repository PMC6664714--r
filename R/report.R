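# Configurable quality-control report: a battery of checks at three
# severity levels (ERROR > WARN > INFO), fail-on logic, TSV/CSV/YAML
# output, and automatic repair of the two mechanically fixable problems
# (duplicate-axiom annotation merging, deprecated-reference rewriting).
#
# Checks are SPARQL SELECT queries returning (subject, property, value);
# the one exception is equivalent_class_pair, which consumes the
# reasoner's taxonomy so that *inferred* (not just asserted) one-to-one
# equivalences between named classes are caught.

LEVEL_RANK <- c(INFO = 1L, WARN = 2L, ERROR = 3L)

check_doc_url <- function(name) {
  paste0("https://owlet-docs.example.org/report/", gsub("_", "-", name))
}

default_check_queries <- function(props) {
  # anonymous class expressions are also typed owl:Class in RDF; every
  # class-scoped check therefore restricts subjects to IRIs
  q <- function(body) {
    paste0(
      "PREFIX owl: <", NS_OWL, ">\n",
      "PREFIX rdfs: <", NS_RDFS, ">\n",
      "SELECT DISTINCT ?subject ?property ?value WHERE {\n",
      "  FILTER(isIRI(?subject))\n", body, "\n}")
  }
  list(
    missing_label = q(sprintf(
      "?subject a owl:Class .
       FILTER NOT EXISTS { ?subject <%s> ?l }
       BIND(<%s> AS ?property)", props$label, props$label)),
    duplicate_label = q(sprintf(
      "?subject a owl:Class ; <%s> ?value .
       ?other a owl:Class ; <%s> ?value .
       FILTER(?other != ?subject)
       BIND(<%s> AS ?property)", props$label, props$label, props$label)),
    duplicate_definition = q(sprintf(
      "?subject a owl:Class ; <%s> ?value .
       ?other a owl:Class ; <%s> ?value .
       FILTER(?other != ?subject)
       BIND(<%s> AS ?property)",
      props$definition, props$definition, props$definition)),
    multiple_definitions = q(sprintf(
      "?subject a owl:Class ; <%s> ?d1 , ?d2 .
       FILTER(?d1 < ?d2)
       BIND(<%s> AS ?property)
       BIND(\"multiple definitions\" AS ?value)",
      props$definition, props$definition)),
    self_reference = q(
      "?subject rdfs:subClassOf ?subject .
       BIND(rdfs:subClassOf AS ?property)
       BIND(\"self reference\" AS ?value)"),
    trailing_whitespace = q(
      "?subject ?property ?value .
       FILTER(isIRI(?subject))
       FILTER(isLiteral(?value))
       FILTER(REGEX(STR(?value), \"^\\\\s|\\\\s$\"))"),
    invalid_xref_syntax = q(sprintf(
      "?subject <%s> ?value .
       FILTER(isIRI(?subject))
       FILTER(!REGEX(STR(?value), \"^[^\\\\s:]+:[^\\\\s]+$\"))
       BIND(<%s> AS ?property)", props$xref, props$xref)),
    missing_ontology_license = q(sprintf(
      "?subject a owl:Ontology .
       FILTER NOT EXISTS { ?subject <%s> ?l }
       BIND(<%s> AS ?property)", props$license, props$license)),
    missing_ontology_title = q(sprintf(
      "?subject a owl:Ontology .
       FILTER NOT EXISTS { ?subject <%s> ?t }
       BIND(<%s> AS ?property)", props$title, props$title)),
    definition_format = q(sprintf(
      "?subject a owl:Class ; <%s> ?value .
       FILTER(!REGEX(STR(?value), \"^[A-Z](.|\\\\n)*\\\\.$\"))
       BIND(<%s> AS ?property)", props$definition, props$definition)),
    missing_definition = q(sprintf(
      "?subject a owl:Class .
       FILTER NOT EXISTS { ?subject <%s> ?d }
       BIND(<%s> AS ?property)", props$definition, props$definition))
  )
}

new_check <- function(name, level, query, doc_url = check_doc_url(name),
                      native = FALSE) {
  list(name = name, level = level, query = query, doc_url = doc_url,
       native = native)
}

#' The built-in QC check battery
#'
#' Severity assignment: ERROR for missing/duplicate labels and
#' definitions (these break tooling and search); WARN for inferred
#' equivalent class pairs, self references, trailing whitespace, invalid
#' cross-reference syntax and missing ontology metadata; INFO for
#' definition style (start uppercase, end with a period) and missing
#' definitions.  Each check carries a documentation link with a suggested
#' manual fix.  Default fail-on level is ERROR.
#'
#' @param props annotation-property configuration, see [obo_properties()].
#' @return An object of class `owlet_profile`: list with `checks` (named
#'   list) and `fail_on` (`"ERROR"`).
#' @export
default_profile <- function(props = obo_properties()) {
  queries <- default_check_queries(props)
  levels <- c(
    missing_label = "ERROR", duplicate_label = "ERROR",
    duplicate_definition = "ERROR", multiple_definitions = "ERROR",
    equivalent_class_pair = "WARN", self_reference = "WARN",
    trailing_whitespace = "WARN", invalid_xref_syntax = "WARN",
    missing_ontology_license = "WARN", missing_ontology_title = "WARN",
    definition_format = "INFO", missing_definition = "INFO")
  checks <- list()
  for (nm in names(levels)) {
    checks[[nm]] <- if (nm == "equivalent_class_pair") {
      new_check(nm, levels[[nm]], query = NULL, native = TRUE)
    } else {
      new_check(nm, levels[[nm]], queries[[nm]])
    }
  }
  structure(list(checks = checks, fail_on = "ERROR", props = props),
            class = "owlet_profile")
}

#' Read a report profile file
#'
#' One check per line: `LEVEL<TAB>name[<TAB>query-path]`, where LEVEL is
#' `ERROR`, `WARN`, `INFO` or `exclude`.  Named checks from the default
#' battery get their level overridden (or are excluded); lines with a
#' query path define custom checks whose SPARQL SELECT is read from that
#' file.  `#` comments and blank lines are allowed, and a
#' `fail_on<TAB>LEVEL` line sets the failure threshold.
#'
#' @param path profile file path.
#' @param base profile to modify (default [default_profile()]).
#' @return An `owlet_profile`.
#' @export
read_profile <- function(path, base = default_profile()) {
  if (!file.exists(path)) {
    owlet_stop("owlet_io_error", sprintf("profile not found: %s", path))
  }
  profile <- base
  for (ln in readLines(path, warn = FALSE)) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (tolower(parts[1]) == "fail_on" && length(parts) == 2) {
      profile$fail_on <- match.arg(parts[2], c("ERROR", "WARN", "INFO", "none"))
      next
    }
    if (length(parts) < 2 ||
        !(parts[1] %in% c("ERROR", "WARN", "INFO", "exclude"))) {
      owlet_stop("owlet_profile_error",
        sprintf("profile: expected 'LEVEL<TAB>name[<TAB>query]', got: %s", ln))
    }
    level <- parts[1]; nm <- parts[2]
    if (level == "exclude") {
      profile$checks[[nm]] <- NULL
      next
    }
    if (length(parts) >= 3) {
      qpath <- parts[3]
      if (!file.exists(qpath)) {
        owlet_stop("owlet_profile_error",
          sprintf("profile: query file for check '%s' not found: %s",
                  nm, qpath))
      }
      query <- paste(readLines(qpath, warn = FALSE), collapse = "\n")
      profile$checks[[nm]] <- new_check(nm, level, query,
                                        doc_url = paste0("file://", qpath))
    } else {
      if (is.null(profile$checks[[nm]])) {
        owlet_stop("owlet_profile_error",
          sprintf("profile: unknown check '%s' (no query path given)", nm))
      }
      profile$checks[[nm]]$level <- level
    }
  }
  profile
}

# native check: inferred one-to-one equivalences between named classes
equivalent_pair_violations <- function(doc) {
  tax <- classify(doc)
  out <- list()
  for (g in tax$nodes) {
    if (length(g$members) < 2) next
    pairs <- utils::combn(sort(g$members), 2)
    for (j in seq_len(ncol(pairs))) {
      out[[length(out) + 1L]] <- c(subject = pairs[1, j],
                                   property = OWL_EQUIVALENTCLASS,
                                   value = pairs[2, j])
    }
  }
  out
}

#' Run the QC report
#'
#' Executes every check in the profile (SPARQL checks in a single engine
#' invocation) and collects violations, each carrying the configured
#' level of its check.  The report fails when any violation is at or
#' above the profile's `fail_on` level (`"none"` never fails).
#'
#' @param doc an ontology document.
#' @param profile an `owlet_profile` (default: the built-in battery).
#' @return A list of class `owlet_report`: `violations` (data.frame with
#'   columns `level`, `rule`, `subject`, `property`, `value`, sorted by
#'   severity, rule, subject) and `failed` (logical).
#' @export
run_report <- function(doc, profile = default_profile()) {
  sparql_checks <- Filter(function(ch) !isTRUE(ch$native), profile$checks)
  queries <- lapply(sparql_checks, `[[`, "query")
  tbls <- if (length(queries)) {
    tryCatch(run_select_many(to_graph_view(doc), queries),
      owlet_sparql_error = function(e) {
        owlet_stop("owlet_profile_error",
          sprintf("a report check query failed to execute: %s",
                  conditionMessage(e)))
      })
  } else list()
  rows <- list()
  add_row <- function(rule, level, subject, property, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, rule = rule, subject = subject,
      property = property, value = value, stringsAsFactors = FALSE)
  }
  for (nm in names(tbls)) {
    ch <- profile$checks[[nm]]
    for (r in tbls[[nm]]$rows) {
      add_row(nm, ch$level, r[["subject"]], r[["property"]], r[["value"]])
    }
  }
  if (!is.null(profile$checks$equivalent_class_pair)) {
    lv <- profile$checks$equivalent_class_pair$level
    for (v in equivalent_pair_violations(doc)) {
      add_row("equivalent_class_pair", lv, v[["subject"]], v[["property"]],
              v[["value"]])
    }
  }
  violations <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(level = character(0), rule = character(0),
               subject = character(0), property = character(0),
               value = character(0), stringsAsFactors = FALSE)
  }
  violations <- violations[order(-LEVEL_RANK[violations$level],
                                 violations$rule, violations$subject,
                                 violations$value), , drop = FALSE]
  rownames(violations) <- NULL
  failed <- profile$fail_on != "none" && any(
    LEVEL_RANK[violations$level] >= LEVEL_RANK[[profile$fail_on]])
  structure(list(violations = violations, failed = failed,
                 fail_on = profile$fail_on),
            class = "owlet_report")
}

#' @export
print.owlet_report <- function(x, ...) {
  tab <- table(x$violations$level)
  cat("<owlet_report>", nrow(x$violations), "violation(s)",
      if (nrow(x$violations)) paste0("(",
        paste(names(tab), tab, sep = ": ", collapse = ", "), ") ") else "",
      "failed:", x$failed, "\n")
  invisible(x)
}

#' Write a report to disk
#'
#' TSV/CSV columns are `level`, `rule`, `subject`, `property`, `value`;
#' YAML output is a list of mappings with the same keys.  Serialization
#' is deterministic.
#'
#' @param report an `owlet_report` (or its violations data.frame).
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "csv", "yaml")) {
  format <- match.arg(format)
  v <- if (inherits(report, "owlet_report")) report$violations else report
  if (format == "yaml") {
    recs <- lapply(seq_len(nrow(v)), function(i) as.list(v[i, ]))
    writeLines(yaml::as.yaml(recs), path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    quote_cell <- function(x) {
      if (format == "csv" && grepl("[\",\n]", x)) {
        paste0("\"", gsub("\"", "\"\"", x), "\"")
      } else x
    }
    lines <- paste(colnames(v), collapse = sep)
    for (i in seq_len(nrow(v))) {
      lines <- c(lines, paste(vapply(unlist(v[i, ]), quote_cell,
                                     character(1)), collapse = sep))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

# ---- repair ----------------------------------------------------------------

#' Automatically repair mechanically fixable problems
#'
#' Two repairs are applied: (1) axioms identical in logical content are
#' collapsed into one axiom carrying the union of their annotations;
#' (2) every logical-axiom reference to a class marked deprecated that
#' carries a replacement annotation is rewritten to the (transitively
#' resolved) replacement.  Annotations on the deprecated terms themselves
#' are retained.  A cycle among replacement annotations is an error.
#'
#' @param doc an ontology document.
#' @param props annotation-property configuration (`deprecated`,
#'   `replaced_by`).
#' @return The repaired document.
#' @export
repair_document <- function(doc, props = obo_properties()) {
  # (2a) build the replacement map
  deprecated <- character(0)
  replacement <- character(0)
  for (ax in doc$axioms) {
    if (ax$type != "annotation") next
    if (ax$property == props$deprecated &&
        tolower(lit_value(ax$value)) == "true") {
      deprecated <- unique(c(deprecated, ax$subject))
    }
    if (ax$property == props$replaced_by) {
      replacement[ax$subject] <- lit_value(ax$value)
    }
  }
  repl_map <- replacement[names(replacement) %in% deprecated]
  resolve <- function(x) {
    seen <- character(0)
    while (x %in% names(repl_map)) {
      if (x %in% seen) {
        owlet_stop("owlet_repair_error",
          sprintf("replacement chain cycle: %s",
                  paste(c(seen, x), collapse = " -> ")),
          list(cycle = c(seen, x)))
      }
      seen <- c(seen, x)
      x <- repl_map[[x]]
    }
    x
  }
  rewrite_ce <- function(ce) {
    switch(ce$kind,
      named = ce_named(resolve(ce$iri)),
      some = ce_some(ce$property, rewrite_ce(ce$filler)),
      and = ce_and(lapply(ce$operands, rewrite_ce)))
  }
  rewritten <- lapply(unname(doc$axioms), function(ax) {
    if (!is_logical_axiom(ax) || !length(repl_map)) return(ax)
    switch(ax$type,
      subclass = ax_subclass(rewrite_ce(ax$sub), rewrite_ce(ax$sup), ax$anns),
      equivalent = ax_equivalent(lapply(ax$members, rewrite_ce), ax$anns),
      disjoint = ax_disjoint(vapply(ax$members, resolve, character(1)),
                             ax$anns),
      subproperty = ax)
  })
  # (1) merge annotations on duplicate axioms (same logical content)
  by_logic <- split(rewritten,
                    vapply(rewritten, logical_key, character(1)))
  merged <- lapply(by_logic, function(group) {
    ax <- group[[1]]
    if (length(group) > 1) {
      all_anns <- do.call(c, lapply(group, `[[`, "anns"))
      ax$anns <- sorted_annotations(all_anns)
    }
    ax
  })
  doc_set_axioms(doc, unname(merged))
}
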