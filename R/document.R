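# The ontology document: the single in-memory object every command reads
# and returns.  Axioms are stored in a list named by axiom_key(), so the
# set is duplicate-free under logical-content + annotation equality and
# membership tests are name lookups.

#' Create an ontology document
#'
#' @param ontology_iri optional ontology IRI.
#' @param version_iri optional version IRI.
#' @param prefixes named character vector mapping prefix to IRI; the
#'   standard RDF/OWL/OBO prefixes are always included.
#' @param imports character vector of imported ontology IRIs (ordered).
#' @param axioms list of axioms (see [ax_subclass()] and friends).
#' @param ontology_annotations list of [annotation_pair()]s on the
#'   ontology header.
#' @return An object of class `owlet_document`.
#' @export
ontology_document <- function(ontology_iri = NULL, version_iri = NULL,
                              prefixes = character(0), imports = character(0),
                              axioms = list(), ontology_annotations = list()) {
  pfx <- default_prefixes()
  if (length(prefixes)) pfx[names(prefixes)] <- unname(prefixes)
  doc <- structure(list(
    ontology_iri = ontology_iri,
    version_iri = version_iri,
    prefixes = pfx,
    imports = imports,
    axioms = list(),
    ontology_annotations = sorted_annotations(ontology_annotations)
  ), class = "owlet_document")
  doc_add_axioms(doc, axioms)
}

#' Add axioms to a document
#'
#' Set semantics: axioms already present (same logical content and same
#' annotations) are not duplicated; axioms sharing logical content but
#' differing in annotations are both kept.
#'
#' @param doc an ontology document.
#' @param axioms list of axioms.
#' @return The updated document.
#' @export
doc_add_axioms <- function(doc, axioms) {
  if (!length(axioms)) return(doc)
  keys <- vapply(axioms, axiom_key, character(1))
  keep <- !duplicated(keys) & !(keys %in% names(doc$axioms))
  add <- axioms[keep]
  names(add) <- keys[keep]
  doc$axioms <- c(doc$axioms, add)
  doc
}

#' Replace the axiom set of a document
#' @param doc an ontology document.
#' @param axioms list of axioms.
#' @return The document with exactly `axioms` (deduplicated).
#' @export
doc_set_axioms <- function(doc, axioms) {
  doc$axioms <- list()
  doc_add_axioms(doc, axioms)
}

doc_has_axiom <- function(doc, ax) axiom_key(ax) %in% names(doc$axioms)

doc_axioms_of_type <- function(doc, types) {
  Filter(function(ax) ax$type %in% types, doc$axioms)
}

# Asserted subclass edges between *named* classes, as a 2-column matrix.
named_subclass_edges <- function(doc) {
  subs <- character(0); sups <- character(0)
  for (ax in doc$axioms) {
    if (ax$type == "subclass" && is_named_ce(ax$sub) && is_named_ce(ax$sup)) {
      subs <- c(subs, ax$sub$iri); sups <- c(sups, ax$sup$iri)
    }
  }
  cbind(sub = subs, sup = sups)
}

#' Signature of a document
#'
#' Partitions every identifier occurring in any axiom into classes, object
#' properties, annotation properties and individuals.  Declared entities
#' take their declared role; undeclared entities are typed by usage
#' position.  An identifier used in two incompatible roles raises a
#' role-conflict error naming the entity.
#'
#' @param doc an ontology document.
#' @return A list of four character vectors (`classes`,
#'   `object_properties`, `annotation_properties`, `individuals`),
#'   pairwise disjoint, of class `owlet_signature`.
#' @export
signature_of <- function(doc) {
  slots <- c("classes", "object_properties", "annotation_properties",
             "individuals")
  acc <- stats::setNames(vector("list", 4), slots)
  for (s in slots) acc[[s]] <- character(0)
  for (ax in doc$axioms) {
    sig <- axiom_signature(ax)
    for (s in slots) acc[[s]] <- c(acc[[s]], sig[[s]])
  }
  acc <- lapply(acc, function(x) sort(unique(x)))
  # Declarations win over usage typing; usage conflicts are errors.
  all_ids <- unlist(acc, use.names = FALSE)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup)) {
    declared <- list()
    for (ax in doc$axioms) {
      if (ax$type == "declaration") declared[[ax$entity]] <- ax$entity_type
    }
    decl_slot <- c(class = "classes", object_property = "object_properties",
                   annotation_property = "annotation_properties",
                   individual = "individuals")
    for (id in dup) {
      roles <- slots[vapply(slots, function(s) id %in% acc[[s]], logical(1))]
      if (length(roles) < 2) next
      if (!is.null(declared[[id]])) {
        keep <- decl_slot[[declared[[id]]]]
        for (s in setdiff(roles, keep)) acc[[s]] <- setdiff(acc[[s]], id)
        if (!(id %in% acc[[keep]])) acc[[keep]] <- sort(c(acc[[keep]], id))
      } else {
        owlet_stop("owlet_role_conflict",
          sprintf("entity <%s> is used in incompatible roles: %s",
                  id, paste(roles, collapse = ", ")),
          list(entity = id, roles = roles))
      }
    }
  }
  structure(acc, class = "owlet_signature")
}

all_signature_iris <- function(doc) {
  sig <- signature_of(doc)
  sort(unique(unlist(sig, use.names = FALSE)))
}

#' Merge two axiom sets
#'
#' Set union under logical-content + annotation equality: axioms equal in
#' logical content but differing in annotations both survive.
#'
#' @param a,b lists of axioms.
#' @return A deduplicated list of axioms.
#' @export
axiom_set_merge <- function(a, b) {
  all <- c(a, b)
  if (!length(all)) return(list())
  keys <- vapply(all, axiom_key, character(1))
  out <- all[!duplicated(keys)]
  names(out) <- keys[!duplicated(keys)]
  out
}

#' @export
print.owlet_document <- function(x, ...) {
  counts <- table(vapply(x$axioms, `[[`, character(1), "type"))
  cat("<owlet_document>",
      if (!is.null(x$ontology_iri)) paste0(" ", x$ontology_iri) else "", "\n",
      sep = "")
  if (!is.null(x$version_iri)) cat("  version: ", x$version_iri, "\n", sep = "")
  if (length(x$imports)) cat("  imports: ", length(x$imports), "\n", sep = "")
  cat("  axioms: ", length(x$axioms),
      if (length(counts)) paste0(" (", paste(names(counts), counts, sep = ": ",
                                             collapse = ", "), ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.owlet_signature <- function(x, ...) {
  cat("<owlet_signature> classes:", length(x$classes),
      "obj-props:", length(x$object_properties),
      "ann-props:", length(x$annotation_properties),
      "individuals:", length(x$individuals), "\n")
  invisible(x)
}
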