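# Whole-document algebra used by release workflows: merge (with optional
# import-closure collapse), entity selection, remove/filter, ontology
# annotation, and axiom-level diff.

#' Merge ontology documents
#'
#' Axiom-set union of the inputs (and, when `collapse_import_closure` is
#' `TRUE`, of their resolved import closures).  The ontology IRI and
#' ontology annotations are taken from the first input; with collapse the
#' output carries no import statements, without it the inputs' imports are
#' preserved.
#'
#' @param docs list of ontology documents (>= 1).
#' @param collapse_import_closure merge resolved imports into the output
#'   (default `TRUE`).
#' @param catalog an `owlet_catalog` for import resolution (required when
#'   collapsing documents that declare imports).
#' @return The merged ontology document.
#' @export
merge_documents <- function(docs, collapse_import_closure = TRUE,
                            catalog = NULL) {
  if (!length(docs)) {
    owlet_stop("owlet_usage_error", "merge requires at least one document")
  }
  first <- docs[[1]]
  axioms <- list()
  prefixes <- character(0)
  imports <- character(0)
  for (d in docs) {
    axioms <- axiom_set_merge(axioms, d$axioms)
    prefixes[names(d$prefixes)] <- unname(d$prefixes)
    imports <- unique(c(imports, d$imports))
    if (collapse_import_closure) {
      for (imp in resolve_imports(d, catalog)) {
        axioms <- axiom_set_merge(axioms, imp$axioms)
        prefixes[names(imp$prefixes)] <- unname(imp$prefixes)
      }
    }
  }
  ontology_document(
    ontology_iri = first$ontology_iri,
    version_iri = first$version_iri,
    prefixes = prefixes,
    imports = if (collapse_import_closure) character(0) else imports,
    axioms = axioms,
    ontology_annotations = first$ontology_annotations)
}

# ---- Selectors -------------------------------------------------------------

#' Entity selectors
#'
#' Build selector objects for [select_entities()]: `self` keeps the
#' current set, `ancestors`/`descendants` follow asserted named subclass
#' edges (excluding the start set), `annotation_match` selects all
#' entities carrying a matching annotation (ignoring the incoming set),
#' `entity_type` restricts to one signature role.
#'
#' @param property annotation property IRI.
#' @param value full annotation value, or a regular expression when
#'   `is_regex` is `TRUE`.
#' @param is_regex interpret `value` as a regular expression.
#' @return A selector object.
#' @export
sel_annotation <- function(property, value, is_regex = FALSE) {
  if (is_regex) {
    ok <- tryCatch({ grepl(value, "probe"); TRUE },
                   condition = function(e) FALSE)
    if (!ok) {
      owlet_stop("owlet_pattern_error",
                 sprintf("invalid regular expression: %s", value))
    }
  }
  structure(list(kind = "annotation_match", property = property,
                 value = value, is_regex = is_regex),
            class = "owlet_selector")
}

#' @rdname sel_annotation
#' @export
sel_self <- function() structure(list(kind = "self"), class = "owlet_selector")

#' @rdname sel_annotation
#' @export
sel_ancestors <- function() {
  structure(list(kind = "ancestors"), class = "owlet_selector")
}

#' @rdname sel_annotation
#' @export
sel_descendants <- function() {
  structure(list(kind = "descendants"), class = "owlet_selector")
}

#' @rdname sel_annotation
#' @param type one of `"class"`, `"object_property"`,
#'   `"annotation_property"`, `"individual"`.
#' @export
sel_entity_type <- function(type) {
  type <- match.arg(type, c("class", "object_property",
                            "annotation_property", "individual"))
  structure(list(kind = "entity_type", type = type), class = "owlet_selector")
}

reachable <- function(edges, start, from_col, to_col) {
  seen <- character(0)
  queue <- start
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    nxt <- setdiff(edges[edges[, from_col] == x, to_col], c(seen, start))
    seen <- unique(c(seen, nxt))
    queue <- c(queue, nxt)
  }
  seen
}

#' Apply selectors to a seed entity set
#'
#' Selectors are applied left to right, each mapping the current entity
#' set to a new one.
#'
#' @param doc an ontology document.
#' @param seed character vector of entity IRIs.
#' @param selectors list of selector objects (see [sel_annotation()]).
#' @return Character vector of selected entity IRIs.
#' @export
select_entities <- function(doc, seed, selectors = list(sel_self())) {
  current <- unique(seed)
  edges <- NULL
  for (sel in selectors) {
    current <- switch(sel$kind,
      self = current,
      ancestors = {
        if (is.null(edges)) edges <- named_subclass_edges(doc)
        reachable(edges, current, "sub", "sup")
      },
      descendants = {
        if (is.null(edges)) edges <- named_subclass_edges(doc)
        reachable(edges, current, "sup", "sub")
      },
      annotation_match = {
        hits <- character(0)
        for (ax in doc$axioms) {
          if (ax$type != "annotation" || ax$property != sel$property) next
          v <- if (is_literal(ax$value)) ax$value$value else ax$value
          match <- if (sel$is_regex) grepl(sel$value, v) else v == sel$value
          if (match) hits <- c(hits, ax$subject)
        }
        unique(hits)
      },
      entity_type = {
        sig <- signature_of(doc)
        slot <- switch(sel$type, class = "classes",
                       object_property = "object_properties",
                       annotation_property = "annotation_properties",
                       individual = "individuals")
        intersect(current, sig[[slot]])
      })
  }
  sort(current)
}

# ---- remove / filter -------------------------------------------------------

AXIOM_TYPE_GROUPS <- list(
  logical = c("subclass", "equivalent", "disjoint", "subproperty"),
  annotation = "annotation",
  declaration = "declaration",
  subclass = "subclass",
  equivalent = "equivalent",
  disjoint = "disjoint",
  all = c("subclass", "equivalent", "disjoint", "subproperty",
          "annotation", "declaration")
)

resolve_axiom_types <- function(types) {
  unknown <- setdiff(types, names(AXIOM_TYPE_GROUPS))
  if (length(unknown) || !length(types)) {
    owlet_stop("owlet_usage_error",
      sprintf("unknown axiom type selector(s): %s",
              paste(unknown, collapse = ", ")))
  }
  unique(unlist(AXIOM_TYPE_GROUPS[types]))
}

axiom_touches <- function(ax, entities) {
  sig <- axiom_signature(ax)
  any(unlist(sig, use.names = FALSE) %in% entities) ||
    (ax$type == "annotation" && ax$subject %in% entities)
}

axiom_class_positions <- function(ax) {
  switch(ax$type,
    subclass = ,
    equivalent = ,
    disjoint = axiom_signature(ax)$classes,
    subproperty = c(ax$sub, ax$sup),
    annotation = ax$subject,
    declaration = ax$entity)
}

#' Remove axioms about a set of entities
#'
#' Removes axioms of the selected types whose signature touches any of
#' the given entities ("remove anything touching X").  Declarations are
#' removed only when the entity is otherwise unreferenced after the other
#' removals.
#'
#' @param doc an ontology document.
#' @param entities character vector of entity IRIs.
#' @param types character vector over `"logical"`, `"annotation"`,
#'   `"declaration"`, `"subclass"`, `"equivalent"`, `"disjoint"`, `"all"`.
#' @return The document with matching axioms removed.
#' @export
remove_axioms <- function(doc, entities, types = "all") {
  sel_types <- resolve_axiom_types(types)
  if (!length(entities)) return(doc)
  keep <- vapply(doc$axioms, function(ax) {
    if (!(ax$type %in% sel_types)) return(TRUE)
    if (ax$type == "declaration") return(TRUE)  # second pass below
    !axiom_touches(ax, entities)
  }, logical(1))
  kept <- doc$axioms[keep]
  if ("declaration" %in% sel_types) {
    referenced <- unique(unlist(lapply(kept, function(ax) {
      if (ax$type == "declaration") return(character(0))
      c(unlist(axiom_signature(ax), use.names = FALSE),
        if (ax$type == "annotation") ax$subject)
    })))
    kept <- Filter(function(ax) {
      !(ax$type == "declaration" && ax$entity %in% entities &&
          !(ax$entity %in% referenced))
    }, kept)
  }
  doc_set_axioms(doc, kept)
}

#' Keep only axioms about a set of entities
#'
#' Copies axioms of the selected types all of whose class-position
#' entities lie in the given set ("keep only what is about my set"),
#' plus declarations for the selected entities.  This is deliberately
#' stricter than [remove_axioms()]'s any-overlap rule: `remove` drops
#' anything touching the set, `filter` keeps only axioms entirely about
#' it, so the two are not set complements of each other.
#'
#' @inheritParams remove_axioms
#' @return A new document containing only the selected axioms.
#' @export
filter_axioms <- function(doc, entities, types = "all") {
  sel_types <- resolve_axiom_types(types)
  kept <- Filter(function(ax) {
    if (!(ax$type %in% sel_types)) return(FALSE)
    if (ax$type == "declaration") return(ax$entity %in% entities)
    cls <- axiom_class_positions(ax)
    length(cls) > 0 && all(cls %in% entities)
  }, doc$axioms)
  ontology_document(ontology_iri = doc$ontology_iri,
                    version_iri = doc$version_iri,
                    prefixes = doc$prefixes,
                    axioms = unname(kept),
                    ontology_annotations = doc$ontology_annotations)
}

# ---- annotate --------------------------------------------------------------

#' Set ontology-level annotations and the version IRI
#'
#' @param doc an ontology document.
#' @param annotations list of [annotation_pair()]s to add to the header.
#' @param version_iri optional version IRI; overwrites an existing one.
#' @return The annotated document (axioms untouched).
#' @export
annotate_document <- function(doc, annotations = list(), version_iri = NULL) {
  if (!is.null(version_iri)) {
    if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", version_iri)) {
      owlet_stop("owlet_usage_error",
        sprintf("malformed version IRI: %s", version_iri))
    }
    doc$version_iri <- version_iri
  }
  doc$ontology_annotations <-
    sorted_annotations(c(doc$ontology_annotations, annotations))
  doc
}

# ---- diff ------------------------------------------------------------------

#' Compare two documents axiom-by-axiom
#'
#' Symmetric axiom-set difference under logical-content + annotation
#' equality.  Comparing axiom sets rather than serialized text avoids
#' spurious differences from serialization behavior.
#'
#' @param left,right ontology documents.
#' @return An object of class `owlet_diff` with sorted axiom-rendering
#'   vectors `only_in_left` and `only_in_right`; both empty iff the
#'   documents' axiom sets are identical.
#' @export
diff_documents <- function(left, right) {
  lk <- names(left$axioms); rk <- names(right$axioms)
  structure(list(
    only_in_left = sort(setdiff(lk, rk)),
    only_in_right = sort(setdiff(rk, lk))
  ), class = "owlet_diff")
}

#' @export
print.owlet_diff <- function(x, ...) {
  if (!length(x$only_in_left) && !length(x$only_in_right)) {
    cat("Ontologies are identical (axiom sets match).\n")
    return(invisible(x))
  }
  if (length(x$only_in_left)) {
    cat(length(x$only_in_left), "axiom(s) only in left:\n")
    cat(paste0("- ", x$only_in_left, collapse = "\n"), "\n")
  }
  if (length(x$only_in_right)) {
    cat(length(x$only_in_right), "axiom(s) only in right:\n")
    cat(paste0("+ ", x$only_in_right, collapse = "\n"), "\n")
  }
  invisible(x)
}

diff_report_text <- function(d) {
  lines <- c(
    sprintf("only_in_left: %d", length(d$only_in_left)),
    paste0("- ", d$only_in_left),
    sprintf("only_in_right: %d", length(d$only_in_right)),
    paste0("+ ", d$only_in_right))
  paste0(paste(lines, collapse = "\n"), "\n")
}
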