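# The transformations surrounding `reason` in a release workflow:
#   relax       — assert each conjunct of an equivalence definition as an
#                 explicit subclass axiom (consumers can then navigate
#                 without a reasoner);
#   reduce      — remove subclass axioms still entailed after their own
#                 deletion (redundancy elimination);
#   materialize — assert entailed existential superclasses with
#                 most-specific named fillers.

#' Relax equivalence axioms into subclass axioms
#'
#' For every equivalence axiom with a named member `A` and another member
#' that is an intersection (or a single expression), adds
#' `A subClassOf C_i` for each top-level conjunct `C_i`.  Input axioms are
#' untouched; the rule is applied symmetrically to every named member, and
#' does not recurse into nested intersections inside fillers.
#'
#' @param doc an ontology document.
#' @return The document plus the derived subclass axioms.
#' @export
relax <- function(doc) {
  added <- list()
  for (ax in doc$axioms) {
    if (ax$type != "equivalent") next
    named_idx <- which(vapply(ax$members, is_named_ce, logical(1)))
    for (i in named_idx) {
      a <- ax$members[[i]]
      for (j in seq_along(ax$members)) {
        if (j == i) next
        m <- ax$members[[j]]
        conjuncts <- if (m$kind == "and") m$operands else list(m)
        for (cj in conjuncts) {
          added[[length(added) + 1L]] <- ax_subclass(a, cj)
        }
      }
    }
  }
  doc_add_axioms(doc, added)
}

#' Remove redundant subclass axioms
#'
#' Deletes an asserted named-class subclass axiom `A subClassOf B` when the
#' rest of the document still entails it *indirectly*: either through a
#' strict named intermediate (`A` strictly below some `C` strictly below
#' `B`), or because `A` and `B` are entailed equivalent (the edge merely
#' duplicates an equivalence).  An edge that remains a *direct*
#' subsumption is kept even when a definition (e.g. an equivalence axiom
#' relaxed into conjunct edges) also entails it — so after [relax()],
#' exactly one copy of each conjunct edge survives.
#'
#' Candidates are processed in deterministic lexicographic
#' (sub IRI, sup IRI) order, greedily and sequentially with re-checking,
#' so interacting redundancies resolve identically on every run.
#' Annotation and equivalence axioms are never touched; logical
#' equivalence of the document is preserved (only entailed axioms are ever
#' removed).
#'
#' @param doc an ontology document.
#' @return The reduced document.
#' @export
reduce <- function(doc) {
  is_candidate <- vapply(doc$axioms, function(ax) {
    ax$type == "subclass" && is_named_ce(ax$sub) && is_named_ce(ax$sup)
  }, logical(1))
  cands <- doc$axioms[is_candidate]
  if (!length(cands)) return(doc)
  ord <- order(vapply(cands, function(ax) ax$sub$iri, character(1)),
               vapply(cands, function(ax) ax$sup$iri, character(1)))
  cands <- cands[ord]
  for (ax in cands) {
    key <- axiom_key(ax)
    if (!(key %in% names(doc$axioms))) next
    trial <- doc
    trial$axioms[[key]] <- NULL
    if (subclass_edge_redundant(trial, ax$sub$iri, ax$sup$iri)) {
      doc <- trial
    }
  }
  doc
}

# Is the named edge a -> b redundant given the document `trial` (which no
# longer contains the edge itself)?
subclass_edge_redundant <- function(trial, a, b) {
  subs <- classify(trial)$subsumptions
  holds <- function(x, y) any(subs$sub == x & subs$sup == y)
  if (!holds(a, b)) return(FALSE)
  if (holds(b, a)) return(TRUE)   # a == b: the edge duplicates an equivalence
  mids <- unique(subs$sup[subs$sub == a])
  mids <- setdiff(mids, c(a, b))
  for (m in mids) {
    if (holds(m, b) && !holds(m, a) && !holds(b, m)) return(TRUE)
  }
  FALSE
}

#' Materialize entailed existential superclasses
#'
#' For each named class `A` and each selected object property `R`, asserts
#' `A subClassOf (R some B)` for every most-specific named filler `B` such
#' that the axiom is entailed and not already asserted.  "Most specific"
#' means no other entailed filler `B'` with `B'` strictly subsumed by `B`;
#' among equivalent fillers the lexicographically least is kept.
#'
#' @param doc an ontology document.
#' @param properties character vector of object property IRIs, or `NULL`
#'   for all object properties in the signature.
#' @return The document plus the materialized axioms.
#' @export
materialize <- function(doc, properties = NULL) {
  tax <- classify(doc)
  if (length(tax$unsatisfiable)) {
    owlet_stop("owlet_incoherent",
      sprintf("ontology is incoherent: %d unsatisfiable class(es): %s",
              length(tax$unsatisfiable),
              paste(tax$unsatisfiable, collapse = ", ")),
      list(unsatisfiable = tax$unsatisfiable))
  }
  if (is.null(properties)) {
    properties <- signature_of(doc)$object_properties
  }
  properties <- sort(unique(properties))
  if (!length(properties)) return(doc)
  res <- entailed_existential_fillers(doc, properties)
  # strict subsumption between named fillers, for the most-specific rule
  subs <- tax$subsumptions
  strictly_below <- function(b2, b1) {
    # b2 strictly below b1: b2 [= b1 entailed and not b1 [= b2
    any(subs$sub == b2 & subs$sup == b1) && !any(subs$sub == b1 & subs$sup == b2)
  }
  equivalent_pair <- function(b1, b2) {
    any(subs$sub == b2 & subs$sup == b1) && any(subs$sub == b1 & subs$sup == b2)
  }
  asserted <- vapply(doc$axioms, logical_key, character(1))
  added <- list()
  for (key in sort(names(res$fillers))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    a <- parts[1]; r <- parts[2]
    bs <- sort(unique(res$fillers[[key]]))
    keep <- logical(length(bs))
    for (i in seq_along(bs)) {
      others <- bs[-i]
      dominated <- any(vapply(others, function(o) strictly_below(o, bs[i]),
                              logical(1)))
      dup_equiv <- any(vapply(others[others < bs[i]], function(o)
        equivalent_pair(o, bs[i]), logical(1)))
      keep[i] <- !dominated && !dup_equiv
    }
    for (b in bs[keep]) {
      cand <- ax_subclass(ce_named(a), ce_some(r, ce_named(b)))
      if (!(logical_key(cand) %in% asserted)) {
        added[[length(added) + 1L]] <- cand
      }
    }
  }
  doc_add_axioms(doc, added)
}
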