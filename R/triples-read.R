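# Interpret an RDF triple set back into the internal document model.
# Constructs outside the supported grammar (owl:unionOf, universal
# restrictions, class assertions on individuals, ...) raise an
# unsupported-axiom error naming the construct — never silently dropped.

UNSUPPORTED_PREDICATES <- c(
  "unionOf", "complementOf", "allValuesFrom", "oneOf", "hasValue",
  "minCardinality", "maxCardinality", "cardinality", "minQualifiedCardinality",
  "maxQualifiedCardinality", "qualifiedCardinality", "propertyChainAxiom",
  "inverseOf", "disjointUnionOf", "hasSelf"
)

#' Interpret RDF triples as an ontology document
#'
#' @param triples a triple data.frame as produced by [doc_to_triples()].
#' @param prefixes named character vector of prefixes for the document.
#' @param source description of the triple origin, used in error messages.
#' @return An ontology document.
#' @export
triples_to_doc <- function(triples, prefixes = character(0), source = "input") {
  tr <- triples
  unsupported <- intersect(paste0(NS_OWL, UNSUPPORTED_PREDICATES), unique(tr$p))
  if (length(unsupported)) {
    owlet_stop("owlet_unsupported_axiom",
      sprintf("%s: unsupported OWL construct(s): %s", source,
              paste(basename(unsupported), collapse = ", ")),
      list(constructs = unsupported))
  }

  by_subject <- split(seq_len(nrow(tr)), tr$s)
  get_po <- function(node) tr[by_subject[[node]], , drop = FALSE]
  obj_values <- function(node, pred) {
    idx <- by_subject[[node]]
    if (is.null(idx)) return(tr[0, , drop = FALSE])
    rows <- tr[idx, , drop = FALSE]
    rows[rows$p == pred, , drop = FALSE]
  }
  one_obj <- function(node, pred) {
    rows <- obj_values(node, pred)
    if (nrow(rows) != 1) {
      owlet_stop("owlet_unsupported_axiom",
        sprintf("%s: expected exactly one <%s> on node %s, found %d",
                source, pred, node, nrow(rows)))
    }
    rows[1, , drop = FALSE]
  }

  read_rdf_list <- function(node) {
    items <- list()
    while (node != RDF_NIL) {
      first <- one_obj(node, RDF_FIRST)
      items[[length(items) + 1L]] <- first
      rest <- one_obj(node, RDF_REST)
      node <- rest$o
    }
    items
  }

  node_to_ce <- function(node, kind) {
    if (kind == "iri") return(ce_named(node))
    rows <- get_po(node)
    types <- rows$o[rows$p == RDF_TYPE]
    if (OWL_RESTRICTION %in% types) {
      prop <- one_obj(node, OWL_ONPROPERTY)
      if (prop$o_kind != "iri") {
        owlet_stop("owlet_unsupported_axiom",
          sprintf("%s: anonymous property in restriction", source))
      }
      filler <- one_obj(node, OWL_SOMEVALUESFROM)
      return(ce_some(prop$o, node_to_ce(filler$o, filler$o_kind)))
    }
    inter <- rows[rows$p == OWL_INTERSECTIONOF, , drop = FALSE]
    if (nrow(inter) == 1) {
      items <- read_rdf_list(inter$o[1])
      ops <- lapply(items, function(it) node_to_ce(it$o, it$o_kind))
      return(ce_and(ops))
    }
    owlet_stop("owlet_unsupported_axiom",
      sprintf("%s: blank-node class expression is neither an existential restriction nor an intersection", source))
  }

  # Structural node census -----------------------------------------------
  bn_types <- tr[tr$s_kind == "bnode" & tr$p == RDF_TYPE, , drop = FALSE]
  axiom_nodes <- bn_types$s[bn_types$o == OWL_AXIOM]
  alldisjoint_nodes <- bn_types$s[bn_types$o == OWL_ALLDISJOINTCLASSES]
  ontology_nodes <- tr$s[tr$p == RDF_TYPE & tr$o == OWL_ONTOLOGY]
  # Blank nodes reachable as expression structure (restrictions, lists).
  structural <- new.env(parent = emptyenv())
  mark_structural <- function(node) {
    if (!startsWith(node, "_:")) return(invisible())
    assign(node, TRUE, envir = structural)
    idx <- by_subject[[node]]
    if (is.null(idx)) return(invisible())
    for (i in idx) {
      if (tr$o_kind[i] == "bnode") mark_structural(tr$o[i])
    }
  }
  for (b in bn_types$s[bn_types$o %in% c(OWL_RESTRICTION, OWL_CLASS)]) {
    mark_structural(b)
  }
  for (b in c(axiom_nodes, alldisjoint_nodes)) mark_structural(b)
  is_structural <- function(node) {
    startsWith(node, "_:") && exists(node, envir = structural)
  }

  # Reified axiom annotations: key (src, p, tgt-rendering) -> list of
  # annotation sets.
  reif <- list()
  row_obj_key <- function(rows, i) {
    if (rows$o_kind[i] == "literal") {
      value_key(literal(rows$o[i],
                        if (is.na(rows$lang[i])) NULL else rows$lang[i],
                        if (is.na(rows$dt[i])) NULL else rows$dt[i]))
    } else paste0("<", rows$o[i], ">")
  }
  for (an in axiom_nodes) {
    src <- one_obj(an, OWL_ANNOTATEDSOURCE)
    prp <- one_obj(an, OWL_ANNOTATEDPROPERTY)
    tgt <- one_obj(an, OWL_ANNOTATEDTARGET)
    rows <- get_po(an)
    keep <- !(rows$p %in% c(RDF_TYPE, OWL_ANNOTATEDSOURCE,
                            OWL_ANNOTATEDPROPERTY, OWL_ANNOTATEDTARGET))
    anns <- lapply(which(keep), function(i) {
      v <- if (rows$o_kind[i] == "literal") {
        literal(rows$o[i], if (is.na(rows$lang[i])) NULL else rows$lang[i],
                if (is.na(rows$dt[i])) NULL else rows$dt[i])
      } else rows$o[i]
      annotation_pair(rows$p[i], v)
    })
    key <- paste0(src$o, "|", prp$o, "|", row_obj_key(tgt, 1))
    reif[[key]] <- c(reif[[key]], list(anns))
  }
  ann_sets_for <- function(s, p, rows, i) {
    key <- paste0(s, "|", p, "|", row_obj_key(rows, i))
    if (!is.null(reif[[key]])) reif[[key]] else list(list())
  }

  # Header ----------------------------------------------------------------
  ontology_iri <- NULL; version_iri <- NULL
  imports <- character(0); ontology_annotations <- list()
  header_node <- NULL
  if (length(ontology_nodes)) {
    header_node <- sort(ontology_nodes)[1]
    if (!startsWith(header_node, "_:")) ontology_iri <- header_node
    rows <- get_po(header_node)
    for (i in seq_len(nrow(rows))) {
      p <- rows$p[i]
      if (p == RDF_TYPE) next
      if (p == OWL_VERSIONIRI) { version_iri <- rows$o[i]; next }
      if (p == OWL_IMPORTS) { imports <- c(imports, rows$o[i]); next }
      v <- if (rows$o_kind[i] == "literal") {
        literal(rows$o[i], if (is.na(rows$lang[i])) NULL else rows$lang[i],
                if (is.na(rows$dt[i])) NULL else rows$dt[i])
      } else rows$o[i]
      ontology_annotations <- c(ontology_annotations,
                                list(annotation_pair(p, v)))
    }
  }

  # Axioms ----------------------------------------------------------------
  decl_map <- stats::setNames(
    c("class", "object_property", "annotation_property", "individual"),
    c(OWL_CLASS, OWL_OBJECTPROPERTY, OWL_ANNOTATIONPROPERTY,
      OWL_NAMEDINDIVIDUAL))
  axioms <- list()
  add <- function(ax) axioms[[length(axioms) + 1L]] <<- ax

  reserved_preds <- c(RDF_TYPE, RDF_FIRST, RDF_REST, RDFS_SUBCLASSOF,
                      RDFS_SUBPROPERTYOF, OWL_EQUIVALENTCLASS,
                      OWL_DISJOINTWITH, OWL_ONPROPERTY, OWL_SOMEVALUESFROM,
                      OWL_INTERSECTIONOF, OWL_MEMBERS, OWL_ANNOTATEDSOURCE,
                      OWL_ANNOTATEDPROPERTY, OWL_ANNOTATEDTARGET,
                      OWL_VERSIONIRI, OWL_IMPORTS)

  for (i in seq_len(nrow(tr))) {
    s <- tr$s[i]; p <- tr$p[i]; o <- tr$o[i]
    s_is_header <- !is.null(header_node) && s == header_node
    # Logical predicates are interpreted even on expression blank nodes
    # (anonymous equivalence members, GCIs); everything else on a
    # structural or header node is part of that structure, not an axiom.
    if (!(p %in% c(RDFS_SUBCLASSOF, OWL_EQUIVALENTCLASS)) &&
        (s_is_header || is_structural(s))) next
    if (p == RDF_TYPE) {
      if (o %in% names(decl_map)) {
        if (tr$s_kind[i] != "iri") next
        for (anns in ann_sets_for(s, p, tr, i)) {
          add(ax_declaration(s, decl_map[[o]], anns))
        }
      } else if (o %in% c(OWL_ONTOLOGY, OWL_AXIOM, OWL_ALLDISJOINTCLASSES,
                          OWL_RESTRICTION)) {
        next
      } else {
        owlet_stop("owlet_unsupported_axiom",
          sprintf("%s: unsupported rdf:type assertion <%s> a <%s>", source, s, o))
      }
    } else if (p == RDFS_SUBCLASSOF) {
      sub <- node_to_ce(s, tr$s_kind[i]); sup <- node_to_ce(o, tr$o_kind[i])
      for (anns in ann_sets_for(s, p, tr, i)) add(ax_subclass(sub, sup, anns))
    } else if (p == OWL_EQUIVALENTCLASS) {
      a <- node_to_ce(s, tr$s_kind[i]); b <- node_to_ce(o, tr$o_kind[i])
      for (anns in ann_sets_for(s, p, tr, i)) {
        add(ax_equivalent(list(a, b), anns))
      }
    } else if (p == OWL_DISJOINTWITH) {
      if (tr$s_kind[i] != "iri" || tr$o_kind[i] != "iri") {
        owlet_stop("owlet_unsupported_axiom",
          sprintf("%s: disjointness between anonymous classes", source))
      }
      for (anns in ann_sets_for(s, p, tr, i)) add(ax_disjoint(c(s, o), anns))
    } else if (p == RDFS_SUBPROPERTYOF) {
      for (anns in ann_sets_for(s, p, tr, i)) add(ax_subproperty(s, o, anns))
    } else if (p %in% reserved_preds) {
      next
    } else {
      if (tr$s_kind[i] != "iri") {
        owlet_stop("owlet_unsupported_axiom",
          sprintf("%s: annotation on blank node with property <%s>", source, p))
      }
      v <- if (tr$o_kind[i] == "literal") {
        literal(o, if (is.na(tr$lang[i])) NULL else tr$lang[i],
                if (is.na(tr$dt[i])) NULL else tr$dt[i])
      } else if (tr$o_kind[i] == "iri") o else {
        owlet_stop("owlet_unsupported_axiom",
          sprintf("%s: blank-node annotation value on <%s>", source, s))
      }
      for (anns in ann_sets_for(s, p, tr, i)) {
        add(ax_annotation(s, p, v, anns))
      }
    }
  }

  # n-ary disjointness
  for (dn in alldisjoint_nodes) {
    members_row <- one_obj(dn, OWL_MEMBERS)
    items <- read_rdf_list(members_row$o)
    iris <- vapply(items, function(it) {
      if (it$o_kind != "iri") {
        owlet_stop("owlet_unsupported_axiom",
          sprintf("%s: anonymous class in AllDisjointClasses", source))
      }
      it$o
    }, character(1))
    rows <- get_po(dn)
    keep <- !(rows$p %in% c(RDF_TYPE, OWL_MEMBERS))
    anns <- lapply(which(keep), function(j) {
      v <- if (rows$o_kind[j] == "literal") {
        literal(rows$o[j], if (is.na(rows$lang[j])) NULL else rows$lang[j],
                if (is.na(rows$dt[j])) NULL else rows$dt[j])
      } else rows$o[j]
      annotation_pair(rows$p[j], v)
    })
    add(ax_disjoint(iris, anns))
  }

  ontology_document(ontology_iri = ontology_iri, version_iri = version_iri,
                    prefixes = prefixes, imports = imports, axioms = axioms,
                    ontology_annotations = ontology_annotations)
}
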