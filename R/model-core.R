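# Core data model: identifiers (IRIs/CURIEs), literals, class expressions,
# axioms, documents.  Everything downstream (IO, reasoning, extraction, QC)
# works on these structures.
#
# Representation notes:
#   * An identifier is a plain character scalar holding the full IRI.
#   * A literal is a list tagged "owlet_literal".
#   * A class expression is a list tagged "owlet_ce" with kind
#     "named" | "some" | "and"; `and` is flattened and its operands sorted,
#     so structural equality up to operand order is string equality of keys.
#   * An axiom is a list tagged "owlet_axiom"; `axiom_key()` renders the
#     full identity (logical content + annotations), `logical_key()` just
#     the logical content, so "duplicate axioms" (same logic, different
#     annotations) are distinguishable — the distinction `repair` relies on.

# ---- CURIEs ----------------------------------------------------------------

#' Expand a CURIE to a full IRI
#'
#' @param x character vector of CURIEs or IRIs; absolute IRIs pass through.
#' @param prefixes named character vector mapping prefix to IRI.
#' @return character vector of full IRIs.
#' @export
expand_curie <- function(x, prefixes) {
  vapply(x, function(s) {
    if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", s) || grepl("^urn:", s) ||
        grepl("^mailto:", s)) {
      return(s)
    }
    m <- regmatches(s, regexec("^([A-Za-z_][A-Za-z0-9_.-]*):(.*)$", s))[[1]]
    if (length(m) == 3 && m[2] %in% names(prefixes)) {
      return(paste0(prefixes[[m[2]]], m[3]))
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Contract a full IRI to a CURIE
#'
#' The longest matching prefix IRI wins; ties are broken lexicographically
#' by prefix name.  IRIs with no matching prefix are returned unchanged.
#'
#' @param x character vector of full IRIs.
#' @param prefixes named character vector mapping prefix to IRI.
#' @return character vector of CURIEs (or original IRIs).
#' @export
contract_iri <- function(x, prefixes) {
  if (length(prefixes)) {
    prefixes <- prefixes[order(-nchar(prefixes), names(prefixes))]
  }
  vapply(x, function(iri) {
    for (i in seq_along(prefixes)) {
      base <- prefixes[[i]]
      if (startsWith(iri, base) && nchar(iri) > nchar(base)) {
        local <- substring(iri, nchar(base) + 1L)
        # local names must survive Turtle re-parsing: no leading/trailing dot
        if (grepl("^[A-Za-z0-9_-]([A-Za-z0-9_.-]*[A-Za-z0-9_-])?$", local)) {
          return(paste0(names(prefixes)[i], ":", local))
        }
      }
    }
    iri
  }, character(1), USE.NAMES = FALSE)
}

# ---- Literals --------------------------------------------------------------

#' Construct a literal value
#'
#' Equality of literals is triple equality of (lexical form, datatype,
#' language tag).
#'
#' @param value lexical form (character scalar).
#' @param lang optional language tag.
#' @param datatype optional datatype IRI.
#' @return An object of class `owlet_literal`.
#' @export
literal <- function(value, lang = NULL, datatype = NULL) {
  stopifnot(is.character(value), length(value) == 1)
  structure(list(value = value, lang = lang, datatype = datatype),
            class = "owlet_literal")
}

is_literal <- function(x) inherits(x, "owlet_literal")

# Canonical rendering of an annotation value (literal or IRI).
value_key <- function(v) {
  if (is_literal(v)) {
    paste0("\"", v$value, "\"",
           if (!is.null(v$lang)) paste0("@", v$lang) else "",
           if (!is.null(v$datatype)) paste0("^^<", v$datatype, ">") else "")
  } else {
    paste0("<", v, ">")
  }
}

# ---- Class expressions -----------------------------------------------------

#' Class expression constructors
#'
#' The supported grammar is the EL fragment: named classes, existential
#' restrictions (`R some C`), and intersections.  Intersections are
#' flattened on construction (no `and` directly inside `and`), operands are
#' deduplicated and sorted canonically, so structural equality up to operand
#' order is equality of [ce_key()] renderings.
#'
#' @param iri full IRI of a named class.
#' @return An object of class `owlet_ce`.
#' @export
ce_named <- function(iri) {
  stopifnot(is.character(iri), length(iri) == 1)
  structure(list(kind = "named", iri = iri), class = "owlet_ce")
}

#' @rdname ce_named
#' @param property object property IRI.
#' @param filler class expression (or bare IRI, coerced to a named class).
#' @export
ce_some <- function(property, filler) {
  filler <- as_ce(filler)
  structure(list(kind = "some", property = property, filler = filler),
            class = "owlet_ce")
}

#' @rdname ce_named
#' @param operands list of class expressions (bare IRIs coerced); nested
#'   intersections are flattened.  A single distinct operand collapses to
#'   that operand.
#' @export
ce_and <- function(operands) {
  ops <- list()
  for (op in operands) {
    op <- as_ce(op)
    if (op$kind == "and") ops <- c(ops, op$operands) else ops <- c(ops, list(op))
  }
  keys <- vapply(ops, ce_key, character(1))
  ops <- ops[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  ops <- ops[order(keys)]
  if (length(ops) == 1) return(ops[[1]])
  stopifnot(length(ops) >= 2)
  structure(list(kind = "and", operands = ops), class = "owlet_ce")
}

as_ce <- function(x) {
  if (inherits(x, "owlet_ce")) x else ce_named(x)
}

is_named_ce <- function(x) inherits(x, "owlet_ce") && x$kind == "named"

#' Canonical rendering of a class expression
#'
#' @param x class expression.
#' @return character scalar; equal iff the expressions are structurally
#'   equal (up to intersection operand order).
#' @export
ce_key <- function(x) {
  switch(x$kind,
    named = paste0("<", x$iri, ">"),
    some  = paste0("some(<", x$property, ">,", ce_key(x$filler), ")"),
    and   = paste0("and(", paste(vapply(x$operands, ce_key, character(1)),
                                 collapse = ","), ")")
  )
}

# All named class IRIs and all property IRIs inside an expression.
ce_signature <- function(x) {
  switch(x$kind,
    named = list(classes = x$iri, properties = character(0)),
    some  = {
      s <- ce_signature(x$filler)
      list(classes = s$classes, properties = c(x$property, s$properties))
    },
    and   = {
      parts <- lapply(x$operands, ce_signature)
      list(
        classes = unique(unlist(lapply(parts, `[[`, "classes"))),
        properties = unique(unlist(lapply(parts, `[[`, "properties")))
      )
    }
  )
}

# ---- Axioms ----------------------------------------------------------------

sorted_annotations <- function(anns) {
  if (!length(anns)) return(list())
  keys <- vapply(anns, function(a) paste0("<", a$property, "> ", value_key(a$value)),
                 character(1))
  anns <- anns[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  anns[order(keys)]
}

#' Axiom annotation
#'
#' A (property, value) pair attached either to an axiom (axiom annotation)
#' or to the ontology header.
#'
#' @param property annotation property IRI.
#' @param value an [literal()] or an IRI string.
#' @return A list with elements `property` and `value`.
#' @export
annotation_pair <- function(property, value) {
  list(property = property, value = value)
}

new_axiom <- function(type, fields, anns = list()) {
  structure(c(list(type = type), fields,
              list(anns = sorted_annotations(anns))),
            class = "owlet_axiom")
}

#' Axiom constructors
#'
#' Logical axioms (`subclass`, `equivalent`, `disjoint`, `subproperty`),
#' annotation assertions and entity declarations.  All constructors accept
#' an `anns` list of [annotation_pair()]s carried as axiom annotations;
#' two axioms may share logical content and differ only in annotations.
#'
#' @param sub,sup class expressions (or IRIs) for subclass; IRIs for
#'   subproperty.
#' @param anns list of axiom annotations.
#' @return An object of class `owlet_axiom`.
#' @export
ax_subclass <- function(sub, sup, anns = list()) {
  new_axiom("subclass", list(sub = as_ce(sub), sup = as_ce(sup)), anns)
}

#' @rdname ax_subclass
#' @param members for `ax_equivalent`, a list of >= 2 class expressions
#'   (unordered); for `ax_disjoint`, >= 2 named class IRIs.
#' @export
ax_equivalent <- function(members, anns = list()) {
  members <- lapply(members, as_ce)
  keys <- vapply(members, ce_key, character(1))
  members <- members[!duplicated(keys)]
  members <- members[order(vapply(members, ce_key, character(1)))]
  stopifnot(length(members) >= 2)
  new_axiom("equivalent", list(members = members), anns)
}

#' @rdname ax_subclass
#' @export
ax_disjoint <- function(members, anns = list()) {
  members <- sort(unique(unlist(members)))
  stopifnot(length(members) >= 2)
  new_axiom("disjoint", list(members = members), anns)
}

#' @rdname ax_subclass
#' @export
ax_subproperty <- function(sub, sup, anns = list()) {
  new_axiom("subproperty", list(sub = sub, sup = sup), anns)
}

#' @rdname ax_subclass
#' @param subject entity IRI being annotated.
#' @param property annotation property IRI.
#' @param value an [literal()] for text values, or a character scalar
#'   holding a full IRI for entity-valued annotations.
#' @export
ax_annotation <- function(subject, property, value, anns = list()) {
  stopifnot(is_literal(value) || (is.character(value) && length(value) == 1))
  new_axiom("annotation",
            list(subject = subject, property = property, value = value), anns)
}

#' @rdname ax_subclass
#' @param entity entity IRI being declared.
#' @param entity_type one of `"class"`, `"object_property"`,
#'   `"annotation_property"`, `"individual"`.
#' @export
ax_declaration <- function(entity, entity_type, anns = list()) {
  entity_type <- match.arg(entity_type,
    c("class", "object_property", "annotation_property", "individual"))
  new_axiom("declaration", list(entity = entity, entity_type = entity_type), anns)
}

#' Canonical axiom identity
#'
#' `logical_key()` renders the logical content only; `axiom_key()` appends
#' the (sorted) axiom annotations, giving full identity under
#' logical-content + annotation equality.
#'
#' @param ax an axiom.
#' @return character scalar.
#' @export
logical_key <- function(ax) {
  switch(ax$type,
    subclass   = paste0("sub(", ce_key(ax$sub), ",", ce_key(ax$sup), ")"),
    equivalent = paste0("equiv(", paste(sort(vapply(ax$members, ce_key,
                         character(1))), collapse = ","), ")"),
    disjoint   = paste0("disj(", paste(sort(ax$members), collapse = ","), ")"),
    subproperty = paste0("subprop(<", ax$sub, ">,<", ax$sup, ">)"),
    annotation = paste0("ann(<", ax$subject, ">,<", ax$property, ">,",
                        value_key(ax$value), ")"),
    declaration = paste0("decl(<", ax$entity, ">,", ax$entity_type, ")")
  )
}

#' @rdname logical_key
#' @export
axiom_key <- function(ax) {
  ann_part <- if (length(ax$anns)) {
    paste0("{", paste(vapply(ax$anns, function(a)
      paste0("<", a$property, ">=", value_key(a$value)), character(1)),
      collapse = ";"), "}")
  } else ""
  paste0(logical_key(ax), ann_part)
}

# Signature of a single axiom: classes, object properties, annotation
# properties (usage-typed), individuals.
axiom_signature <- function(ax) {
  empty <- list(classes = character(0), object_properties = character(0),
                annotation_properties = character(0), individuals = character(0))
  switch(ax$type,
    subclass = {
      a <- ce_signature(ax$sub); b <- ce_signature(ax$sup)
      empty$classes <- unique(c(a$classes, b$classes))
      empty$object_properties <- unique(c(a$properties, b$properties))
      empty
    },
    equivalent = {
      parts <- lapply(ax$members, ce_signature)
      empty$classes <- unique(unlist(lapply(parts, `[[`, "classes")))
      empty$object_properties <- unique(unlist(lapply(parts, `[[`, "properties")))
      empty
    },
    disjoint = { empty$classes <- ax$members; empty },
    subproperty = { empty$object_properties <- c(ax$sub, ax$sup); empty },
    annotation = {
      empty$annotation_properties <- ax$property
      empty
    },
    declaration = {
      slot <- switch(ax$entity_type, class = "classes",
                     object_property = "object_properties",
                     annotation_property = "annotation_properties",
                     individual = "individuals")
      empty[[slot]] <- ax$entity
      empty
    }
  )
}

is_logical_axiom <- function(ax) {
  ax$type %in% c("subclass", "equivalent", "disjoint", "subproperty")
}

#' @export
print.owlet_axiom <- function(x, ...) {
  cat(axiom_key(x), "\n")
  invisible(x)
}

#' @export
print.owlet_ce <- function(x, ...) {
  cat(ce_key(x), "\n")
  invisible(x)
}
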