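# Document <-> RDF triple mapping, following the standard OWL-to-RDF graph
# patterns: anonymous class expressions become blank nodes (owl:Restriction
# / owl:intersectionOf lists), axiom annotations use the owl:Axiom
# reification pattern, n-ary disjointness uses owl:AllDisjointClasses.
#
# Triples are a data.frame with columns:
#   s, s_kind ("iri"|"bnode"), p, o, o_kind ("iri"|"bnode"|"literal"),
#   lang, dt (NA when absent).
# Triple generation order is a pure function of the document (axioms are
# pre-sorted, blank-node labels allocated sequentially), which is what
# makes the serializers byte-deterministic.

empty_triples <- function() {
  data.frame(s = character(0), s_kind = character(0), p = character(0),
             o = character(0), o_kind = character(0), lang = character(0),
             dt = character(0), stringsAsFactors = FALSE)
}

axiom_variant_rank <- function(type) {
  match(type, c("declaration", "subclass", "equivalent", "disjoint",
                "subproperty", "annotation"))
}

sorted_axioms <- function(doc) {
  axs <- doc$axioms
  if (!length(axs)) return(list())
  ranks <- vapply(axs, function(a) axiom_variant_rank(a$type), numeric(1))
  keys <- vapply(axs, axiom_key, character(1))
  axs[order(ranks, keys)]
}

new_triple_sink <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$bcount <- 0L
  env
}

sink_emit <- function(sink, s, s_kind, p, o, o_kind, lang = NA_character_,
                      dt = NA_character_) {
  sink$rows[[length(sink$rows) + 1L]] <-
    list(s = s, s_kind = s_kind, p = p, o = o, o_kind = o_kind,
         lang = lang, dt = dt)
}

sink_bnode <- function(sink) {
  sink$bcount <- sink$bcount + 1L
  sprintf("_:b%d", sink$bcount)
}

sink_frame <- function(sink) {
  if (!length(sink$rows)) return(empty_triples())
  do.call(rbind, lapply(sink$rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

# Emit object-position value; returns c(o, o_kind, lang, dt).
obj_of <- function(v) {
  if (is_literal(v)) {
    c(v$value, "literal",
      if (is.null(v$lang)) NA_character_ else v$lang,
      if (is.null(v$datatype)) NA_character_ else v$datatype)
  } else {
    c(v, "iri", NA_character_, NA_character_)
  }
}

# Emit the triples realizing a class expression; returns its node id + kind.
emit_ce <- function(sink, ce) {
  if (ce$kind == "named") return(c(ce$iri, "iri"))
  b <- sink_bnode(sink)
  if (ce$kind == "some") {
    sink_emit(sink, b, "bnode", RDF_TYPE, OWL_RESTRICTION, "iri")
    sink_emit(sink, b, "bnode", OWL_ONPROPERTY, ce$property, "iri")
    f <- emit_ce(sink, ce$filler)
    sink_emit(sink, b, "bnode", OWL_SOMEVALUESFROM, f[1], f[2])
  } else { # and
    sink_emit(sink, b, "bnode", RDF_TYPE, OWL_CLASS, "iri")
    nodes <- lapply(ce$operands, function(op) emit_ce(sink, op))
    lst <- emit_rdf_list(sink, nodes)
    sink_emit(sink, b, "bnode", OWL_INTERSECTIONOF, lst[1], lst[2])
  }
  c(b, "bnode")
}

emit_rdf_list <- function(sink, nodes) {
  if (!length(nodes)) return(c(RDF_NIL, "iri"))
  head <- sink_bnode(sink)
  cur <- head
  for (i in seq_along(nodes)) {
    sink_emit(sink, cur, "bnode", RDF_FIRST, nodes[[i]][1], nodes[[i]][2])
    if (i < length(nodes)) {
      nxt <- sink_bnode(sink)
      sink_emit(sink, cur, "bnode", RDF_REST, nxt, "bnode")
      cur <- nxt
    } else {
      sink_emit(sink, cur, "bnode", RDF_REST, RDF_NIL, "iri")
    }
  }
  c(head, "bnode")
}

# `tgt` is c(value, kind) for node targets or c(value, kind, lang, dt)
# for literal targets.
emit_reification <- function(sink, src, prop, tgt, anns) {
  b <- sink_bnode(sink)
  if (length(tgt) < 4) tgt <- c(tgt, NA_character_, NA_character_)
  sink_emit(sink, b, "bnode", RDF_TYPE, OWL_AXIOM, "iri")
  sink_emit(sink, b, "bnode", OWL_ANNOTATEDSOURCE, src[1], src[2])
  sink_emit(sink, b, "bnode", OWL_ANNOTATEDPROPERTY, prop, "iri")
  sink_emit(sink, b, "bnode", OWL_ANNOTATEDTARGET, tgt[1], tgt[2], tgt[3], tgt[4])
  for (a in anns) {
    o <- obj_of(a$value)
    sink_emit(sink, b, "bnode", a$property, o[1], o[2], o[3], o[4])
  }
}

emit_base_and_annotations <- function(sink, src, prop, tgt, anns) {
  sink_emit(sink, src[1], src[2], prop, tgt[1], tgt[2])
  if (length(anns)) emit_reification(sink, src, prop, tgt, anns)
}

#' Render a document as RDF triples
#'
#' @param doc an ontology document.
#' @param include_header include the ontology header (IRI, version,
#'   imports, ontology annotations).
#' @return A data.frame of triples (columns `s`, `s_kind`, `p`, `o`,
#'   `o_kind`, `lang`, `dt`).
#' @export
doc_to_triples <- function(doc, include_header = TRUE) {
  sink <- new_triple_sink()
  if (include_header &&
      (!is.null(doc$ontology_iri) || !is.null(doc$version_iri) ||
       length(doc$imports) || length(doc$ontology_annotations))) {
    onode <- if (!is.null(doc$ontology_iri)) c(doc$ontology_iri, "iri")
             else c(sink_bnode(sink), "bnode")
    sink_emit(sink, onode[1], onode[2], RDF_TYPE, OWL_ONTOLOGY, "iri")
    if (!is.null(doc$version_iri)) {
      sink_emit(sink, onode[1], onode[2], OWL_VERSIONIRI, doc$version_iri, "iri")
    }
    for (imp in doc$imports) {
      sink_emit(sink, onode[1], onode[2], OWL_IMPORTS, imp, "iri")
    }
    for (a in doc$ontology_annotations) {
      o <- obj_of(a$value)
      sink_emit(sink, onode[1], onode[2], a$property, o[1], o[2], o[3], o[4])
    }
  }
  decl_type <- c(class = OWL_CLASS, object_property = OWL_OBJECTPROPERTY,
                 annotation_property = OWL_ANNOTATIONPROPERTY,
                 individual = OWL_NAMEDINDIVIDUAL)
  for (ax in sorted_axioms(doc)) {
    switch(ax$type,
      declaration = {
        s <- c(ax$entity, "iri")
        emit_base_and_annotations(sink, s, RDF_TYPE,
                                  c(decl_type[[ax$entity_type]], "iri"), ax$anns)
      },
      subclass = {
        src <- emit_ce(sink, ax$sub)
        tgt <- emit_ce(sink, ax$sup)
        emit_base_and_annotations(sink, src, RDFS_SUBCLASSOF, tgt, ax$anns)
      },
      equivalent = {
        nodes <- lapply(ax$members, function(m) emit_ce(sink, m))
        for (i in seq_len(length(nodes) - 1L)) {
          emit_base_and_annotations(sink, nodes[[i]], OWL_EQUIVALENTCLASS,
                                    nodes[[i + 1L]], ax$anns)
        }
      },
      disjoint = {
        if (length(ax$members) == 2) {
          emit_base_and_annotations(sink, c(ax$members[1], "iri"),
                                    OWL_DISJOINTWITH,
                                    c(ax$members[2], "iri"), ax$anns)
        } else {
          b <- sink_bnode(sink)
          sink_emit(sink, b, "bnode", RDF_TYPE, OWL_ALLDISJOINTCLASSES, "iri")
          lst <- emit_rdf_list(sink, lapply(ax$members, function(m) c(m, "iri")))
          sink_emit(sink, b, "bnode", OWL_MEMBERS, lst[1], lst[2])
          for (a in ax$anns) {
            o <- obj_of(a$value)
            sink_emit(sink, b, "bnode", a$property, o[1], o[2], o[3], o[4])
          }
        }
      },
      subproperty = {
        emit_base_and_annotations(sink, c(ax$sub, "iri"), RDFS_SUBPROPERTYOF,
                                  c(ax$sup, "iri"), ax$anns)
      },
      annotation = {
        o <- obj_of(ax$value)
        sink_emit(sink, ax$subject, "iri", ax$property, o[1], o[2], o[3], o[4])
        if (length(ax$anns)) {
          emit_reification(sink, c(ax$subject, "iri"), ax$property, o, ax$anns)
        }
      }
    )
  }
  sink_frame(sink)
}
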