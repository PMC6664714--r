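# RDF/XML serialization (deterministic string building) and parsing (xml2).
# The writer emits one rdf:Description block per subject, objects via
# rdf:resource / rdf:nodeID, blank nodes via rdf:nodeID; no typed node
# elements, no parseType shortcuts — a small deterministic dialect.  The
# reader additionally accepts typed node elements and nested Descriptions,
# which other tools commonly produce.

xml_escape <- function(x, attr = FALSE) {
  x <- gsub("&", "&amp;", x)
  x <- gsub("<", "&lt;", x)
  x <- gsub(">", "&gt;", x)
  if (attr) x <- gsub("\"", "&quot;", x)
  x
}

# Split an IRI into (namespace, NCName local); NULL when impossible.
split_iri_ncname <- function(iri) {
  m <- regmatches(iri, regexpr("[A-Za-z_][A-Za-z0-9_.-]*$", iri))
  if (!length(m) || !nchar(m)) return(NULL)
  local <- m
  ns <- substr(iri, 1, nchar(iri) - nchar(local))
  if (!nchar(ns) || !grepl("[#/:]$", ns)) return(NULL)
  list(ns = ns, local = local)
}

#' Serialize triples as RDF/XML text
#'
#' @param triples triple data.frame.
#' @param prefixes named character vector of prefixes.
#' @return Character scalar of RDF/XML text.
#' @export
triples_to_rdfxml <- function(triples, prefixes) {
  pfx <- default_prefixes()
  if (length(prefixes)) pfx[names(prefixes)] <- unname(prefixes)
  # Every predicate needs a declared namespace with an NCName local part.
  preds <- unique(c(triples$p, RDF_TYPE))
  extra <- 0L
  for (p in sort(preds)) {
    parts <- split_iri_ncname(p)
    if (is.null(parts)) {
      owlet_stop("owlet_serialization_error",
        sprintf("rdfxml: predicate <%s> cannot be written as an XML name", p))
    }
    if (!(parts$ns %in% pfx)) {
      extra <- extra + 1L
      pfx[paste0("ns", extra)] <- parts$ns
    }
  }
  pfx <- pfx[order(names(pfx))]
  qname <- function(iri) {
    parts <- split_iri_ncname(iri)
    hit <- names(pfx)[match(parts$ns, pfx)]
    paste0(hit, ":", parts$local)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<rdf:RDF",
             vapply(names(pfx), function(nm)
               sprintf("    xmlns:%s=\"%s\"", nm, xml_escape(pfx[[nm]], TRUE)),
               character(1)))
  lines[length(lines)] <- paste0(lines[length(lines)], ">")
  for (subj in unique(triples$s)) {
    rows <- triples[triples$s == subj, , drop = FALSE]
    sattr <- if (rows$s_kind[1] == "bnode") {
      sprintf("rdf:nodeID=\"%s\"", substring(subj, 3))
    } else {
      sprintf("rdf:about=\"%s\"", xml_escape(subj, TRUE))
    }
    lines <- c(lines, sprintf("  <rdf:Description %s>", sattr))
    for (i in seq_len(nrow(rows))) {
      q <- qname(rows$p[i])
      if (rows$o_kind[i] == "iri") {
        lines <- c(lines, sprintf("    <%s rdf:resource=\"%s\"/>", q,
                                  xml_escape(rows$o[i], TRUE)))
      } else if (rows$o_kind[i] == "bnode") {
        lines <- c(lines, sprintf("    <%s rdf:nodeID=\"%s\"/>", q,
                                  substring(rows$o[i], 3)))
      } else {
        attrs <- ""
        if (!is.na(rows$lang[i])) {
          attrs <- sprintf(" xml:lang=\"%s\"", rows$lang[i])
        } else if (!is.na(rows$dt[i])) {
          attrs <- sprintf(" rdf:datatype=\"%s\"", xml_escape(rows$dt[i], TRUE))
        }
        lines <- c(lines, sprintf("    <%s%s>%s</%s>", q, attrs,
                                  xml_escape(rows$o[i]), q))
      }
    }
    lines <- c(lines, "  </rdf:Description>")
  }
  lines <- c(lines, "</rdf:RDF>")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse RDF/XML text into triples
#'
#' @param text RDF/XML document text.
#' @return A list with `triples` and `prefixes`.
#' @export
parse_rdfxml <- function(text) {
  docx <- xml2::read_xml(text)
  sink <- new_triple_sink()
  ns_defs <- xml2::xml_ns(docx)
  prefixes <- stats::setNames(as.character(ns_defs), names(ns_defs))
  # xml2 names undeclared/default namespaces d1, d2, ...: not real prefixes
  prefixes <- prefixes[!grepl("^d[0-9]+$", names(prefixes))]
  fresh <- function() {
    sink$bcount <- sink$bcount + 1L
    sprintf("_:g%d", sink$bcount)
  }
  # xml2 matches attributes by local name (namespace prefix stripped)
  attr_of <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }
  elem_iri <- function(node) {
    # namespace-resolved element name "ns_prefix:local" -> IRI
    full <- xml2::xml_name(node, ns = ns_defs)
    m <- regmatches(full, regexec("^([^:]+):(.*)$", full))[[1]]
    if (length(m) == 3 && m[2] %in% names(ns_defs)) {
      paste0(ns_defs[[m[2]]], m[3])
    } else full
  }

  parse_node_element <- function(node) {
    about <- attr_of(node, "about")
    nodeid <- attr_of(node, "nodeID")
    subj <- if (!is.null(about)) c(about, "iri")
            else if (!is.null(nodeid)) c(paste0("_:p", nodeid), "bnode")
            else c(fresh(), "bnode")
    eiri <- elem_iri(node)
    if (eiri != paste0(NS_RDF, "Description")) {
      sink_emit(sink, subj[1], subj[2], RDF_TYPE, eiri, "iri")
    }
    for (prop in xml2::xml_children(node)) {
      p <- elem_iri(prop)
      res <- attr_of(prop, "resource")
      pid <- attr_of(prop, "nodeID")
      dt <- attr_of(prop, "datatype")
      lang <- attr_of(prop, "lang")
      kids <- xml2::xml_children(prop)
      if (!is.null(res)) {
        sink_emit(sink, subj[1], subj[2], p, res, "iri")
      } else if (!is.null(pid)) {
        sink_emit(sink, subj[1], subj[2], p, paste0("_:p", pid), "bnode")
      } else if (length(kids)) {
        child <- parse_node_element(kids[[1]])
        sink_emit(sink, subj[1], subj[2], p, child[1], child[2])
      } else {
        sink_emit(sink, subj[1], subj[2], p, xml2::xml_text(prop), "literal",
                  if (is.null(lang)) NA_character_ else lang,
                  if (is.null(dt)) NA_character_ else dt)
      }
    }
    subj
  }

  for (top in xml2::xml_children(docx)) parse_node_element(top)
  list(triples = sink_frame(sink), prefixes = prefixes)
}
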