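# Module extraction: MIREOT (minimal-information term import) and
# syntactic-locality module extraction (BOT / TOP / STAR).
#
# The locality test is syntactic bottom/top-locality over the supported
# grammar: out-of-signature class names are replaced by Bottom (bot
# variant) or Top (top variant), out-of-signature properties make their
# restriction collapse the same way, the expression is simplified, and an
# axiom is local iff it becomes a tautology.  Extraction iterates the
# standard grow-signature loop; STAR alternates bottom and top extraction
# to a fixpoint, which guarantees STAR modules are subsets of both.

# Evaluate bottom-locality status of an expression wrt signature sigma.
# Returns "bot" (interpreted as Bottom), "top" (as Top), or "other".
ce_locality_value <- function(ce, sigma_classes, sigma_props, mode) {
  if (ce$kind == "named") {
    if (ce$iri == OWL_NOTHING) return("bot")
    if (ce$iri == OWL_THING) return("top")
    if (ce$iri %in% sigma_classes) return("other")
    return(if (mode == "bot") "bot" else "top")
  }
  if (ce$kind == "some") {
    filler <- ce_locality_value(ce$filler, sigma_classes, sigma_props, mode)
    if (filler == "bot") return("bot")          # Er.Bottom == Bottom
    if (!(ce$property %in% sigma_props)) {
      # bottom property: restriction empty; top property: restriction is
      # Top only when the filler already is
      return(if (mode == "bot") "bot"
             else if (filler == "top") "top" else "other")
    }
    return("other")
  }
  # and
  vals <- vapply(ce$operands, ce_locality_value,
                 character(1), sigma_classes, sigma_props, mode)
  if (any(vals == "bot")) return("bot")
  if (all(vals == "top")) return("top")
  "other"
}

axiom_is_local <- function(ax, sigma_classes, sigma_props, mode) {
  if (ax$type == "subclass") {
    sub <- ce_locality_value(ax$sub, sigma_classes, sigma_props, mode)
    sup <- ce_locality_value(ax$sup, sigma_classes, sigma_props, mode)
    return(sub == "bot" || sup == "top")
  }
  if (ax$type == "equivalent") {
    vals <- vapply(ax$members, ce_locality_value,
                   character(1), sigma_classes, sigma_props, mode)
    return(all(vals == "bot") || all(vals == "top"))
  }
  if (ax$type == "disjoint") {
    vals <- vapply(ax$members, function(m)
      ce_locality_value(ce_named(m), sigma_classes, sigma_props, mode),
      character(1))
    return(sum(vals != "bot") <= 1)
  }
  if (ax$type == "subproperty") {
    return(if (mode == "bot") !(ax$sub %in% sigma_props)
           else !(ax$sup %in% sigma_props))
  }
  TRUE  # declarations/annotations carry no logical content
}

slme_once <- function(logical_axioms, seed_classes, seed_props, mode) {
  sigma_c <- seed_classes; sigma_p <- seed_props
  in_module <- rep(FALSE, length(logical_axioms))
  repeat {
    changed <- FALSE
    for (i in seq_along(logical_axioms)) {
      if (in_module[i]) next
      if (!axiom_is_local(logical_axioms[[i]], sigma_c, sigma_p, mode)) {
        in_module[i] <- TRUE
        sig <- axiom_signature(logical_axioms[[i]])
        sigma_c <- unique(c(sigma_c, sig$classes))
        sigma_p <- unique(c(sigma_p, sig$object_properties))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(axioms = logical_axioms[in_module], classes = sigma_c,
       props = sigma_p)
}

#' Extract a syntactic-locality module
#'
#' `bot` includes all relationships between the seed entities and their
#' ancestors; `top` those between the seed and its descendants; `star`
#' alternates the two to a fixpoint and produces the smallest output — a
#' subset of both.  Modules preserve every entailment over the seed
#' signature.  The module carries the selected logical axioms, annotation
#' axioms on module entities, and declarations for the module signature.
#'
#' @param doc an ontology document.
#' @param seed character vector of seed entity IRIs (nonempty; unknown
#'   terms are an error).
#' @param method `"bot"`, `"top"` or `"star"`.
#' @return An ontology document (the module).
#' @export
extract_slme <- function(doc, seed, method = c("bot", "top", "star")) {
  method <- match.arg(method)
  sig <- signature_of(doc)
  known <- unique(unlist(sig, use.names = FALSE))
  unknown <- setdiff(seed, known)
  if (length(unknown) || !length(seed)) {
    owlet_stop("owlet_unknown_term",
      sprintf("seed term(s) not in ontology signature: %s",
              paste(if (length(unknown)) unknown else "(empty seed)",
                    collapse = ", ")),
      list(terms = unknown))
  }
  seed_classes <- intersect(seed, sig$classes)
  seed_props <- intersect(seed, sig$object_properties)
  logical_axioms <- unname(Filter(is_logical_axiom, doc$axioms))

  if (method %in% c("bot", "top")) {
    res <- slme_once(logical_axioms, seed_classes, seed_props, method)
    axs <- res$axioms
  } else {
    axs <- logical_axioms
    repeat {  # alternate bot and top extraction to a fixpoint
      a1 <- slme_once(axs, seed_classes, seed_props, "bot")$axioms
      a2 <- slme_once(a1, seed_classes, seed_props, "top")$axioms
      if (length(a2) == length(axs)) break
      axs <- a2
    }
  }
  module_from_axioms(doc, axs, seed)
}

# Assemble a module document: logical axioms + annotations on module
# entities + declarations for the module signature.
module_from_axioms <- function(doc, logical_axioms, seed) {
  sig_entities <- unique(c(seed, unlist(lapply(logical_axioms, function(ax) {
    s <- axiom_signature(ax)
    c(s$classes, s$object_properties)
  }))))
  extra <- Filter(function(ax) {
    (ax$type == "declaration" && ax$entity %in% sig_entities) ||
      (ax$type == "annotation" && ax$subject %in% sig_entities)
  }, doc$axioms)
  ontology_document(ontology_iri = doc$ontology_iri,
                    prefixes = doc$prefixes,
                    axioms = c(logical_axioms, unname(extra)))
}

#' Extract a MIREOT module
#'
#' Copies the specified bottom-level terms and their ancestors along
#' asserted named subclass edges, up to (and including) any top-level
#' terms; with no top terms, ancestors up to the root are included.
#' Following the minimal-information principle, only declarations, labels,
#' textual definitions and the retained subclass edges are copied.
#'
#' @param doc an ontology document.
#' @param bottom_terms character vector of term IRIs (nonempty; terms
#'   absent from the document are an error).
#' @param top_terms optional character vector of IRIs at which upward
#'   traversal stops (the top terms themselves are retained).
#' @param props annotation-property configuration; `label` and
#'   `definition` select the annotations copied.
#' @return An ontology document (the module).
#' @export
extract_mireot <- function(doc, bottom_terms, top_terms = character(0),
                           props = obo_properties()) {
  sig <- signature_of(doc)
  unknown <- setdiff(bottom_terms, sig$classes)
  if (length(unknown) || !length(bottom_terms)) {
    owlet_stop("owlet_unknown_term",
      sprintf("bottom term(s) not in ontology: %s",
              paste(if (length(unknown)) unknown else "(none given)",
                    collapse = ", ")),
      list(terms = unknown))
  }
  edges <- named_subclass_edges(doc)
  keep <- character(0)
  queue <- bottom_terms
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    if (x %in% keep) next
    keep <- c(keep, x)
    if (x %in% top_terms) next   # include, but do not expand beyond
    parents <- edges[edges[, "sub"] == x, "sup"]
    queue <- c(queue, setdiff(parents, keep))
  }
  axs <- list()
  for (x in sort(keep)) axs[[length(axs) + 1L]] <- ax_declaration(x, "class")
  for (ax in doc$axioms) {
    if (ax$type == "subclass" && is_named_ce(ax$sub) && is_named_ce(ax$sup) &&
        ax$sub$iri %in% keep && ax$sup$iri %in% keep) {
      axs[[length(axs) + 1L]] <- ax_subclass(ax$sub, ax$sup)
    }
    if (ax$type == "annotation" && ax$subject %in% keep &&
        ax$property %in% c(props$label, props$definition)) {
      axs[[length(axs) + 1L]] <- ax
    }
  }
  ontology_document(ontology_iri = doc$ontology_iri, prefixes = doc$prefixes,
                    axioms = axs)
}

#' Annotate module terms with their source ontology
#'
#' Adds one provenance annotation per declared entity pointing at the
#' source ontology IRI.  Idempotent: existing source annotations are not
#' duplicated.
#'
#' @param module an ontology document.
#' @param source_iri IRI of the source ontology (required).
#' @param props annotation-property configuration; `source` is the
#'   provenance property used (default `rdfs:isDefinedBy`).
#' @return The annotated module.
#' @export
annotate_sources <- function(module, source_iri, props = obo_properties()) {
  if (is.null(source_iri) || !nzchar(source_iri)) {
    owlet_stop("owlet_usage_error",
               "annotate_sources requires a source ontology IRI")
  }
  entities <- sort(unique(vapply(
    Filter(function(ax) ax$type == "declaration", module$axioms),
    `[[`, character(1), "entity")))
  added <- lapply(entities, function(e)
    ax_annotation(e, props$source, source_iri))
  doc_add_axioms(module, added)
}

#' Extract a module (method dispatch)
#'
#' One entry point over the four extraction methods.
#'
#' @param doc an ontology document.
#' @param method `"mireot"`, `"bot"`, `"top"` or `"star"`.
#' @param seed seed IRIs (locality methods).
#' @param bottom_terms,top_terms MIREOT term sets.
#' @param annotate_with_source add provenance annotations.
#' @param source_iri source ontology IRI (defaults to the document's).
#' @param props annotation-property configuration.
#' @return An ontology document (the module).
#' @export
extract_module <- function(doc, method, seed = character(0),
                           bottom_terms = character(0),
                           top_terms = character(0),
                           annotate_with_source = FALSE, source_iri = NULL,
                           props = obo_properties()) {
  method <- match.arg(method, c("mireot", "bot", "top", "star"))
  mod <- if (method == "mireot") {
    extract_mireot(doc, bottom_terms, top_terms, props)
  } else {
    extract_slme(doc, seed, method)
  }
  if (annotate_with_source) {
    if (is.null(source_iri)) source_iri <- doc$ontology_iri
    mod <- annotate_sources(mod, source_iri, props)
  }
  mod
}
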