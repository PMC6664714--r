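# OBO flat-file 1.4 reader/writer for the expressible subset:
#   class/object-property declarations ([Term]/[Typedef] stanzas),
#   name (label), def (definition + xref list), is_a between named classes,
#   relationship: for A subClassOf (R some B) with named B,
#   equivalent_to (named) and intersection_of (genus-differentia) forms,
#   subset, xref, is_obsolete, replaced_by.
# Everything else is flagged non-expressible: writing it is an error unless
# `lossy = TRUE`, and nothing is ever silently dropped on reading (unknown
# tags are errors).
#
# ID mapping: OBO-library IRIs <NS_OBO><PFX>_<LOCAL> render as PFX:LOCAL;
# other IRIs contract under the document prefix map (declared in the header
# as idspace lines) and full IRIs pass through verbatim.  The version IRI
# is carried verbatim in the data-version header line.

obo_id <- function(iri, prefixes) {
  if (startsWith(iri, NS_OBO)) {
    local <- substring(iri, nchar(NS_OBO) + 1L)
    m <- regmatches(local, regexec("^([A-Za-z][A-Za-z0-9]*)_(.+)$", local))[[1]]
    if (length(m) == 3) return(paste0(m[2], ":", m[3]))
  }
  contract_iri(iri, prefixes)
}

obo_expand_id <- function(id, prefixes) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", id)) return(id)
  m <- regmatches(id, regexec("^([A-Za-z_][A-Za-z0-9_.-]*):(.*)$", id))[[1]]
  if (length(m) == 3) {
    if (m[2] %in% names(prefixes)) return(paste0(prefixes[[m[2]]], m[3]))
    return(paste0(NS_OBO, m[2], "_", m[3]))
  }
  id
}

lit_value <- function(v) if (is_literal(v)) v$value else v

# Classify one axiom: returns the OBO tag name it maps to, or NA if the
# axiom is outside the expressible subset.
obo_axiom_tag <- function(ax, props) {
  if (ax$type == "declaration") {
    if (length(ax$anns)) return(NA_character_)
    return(switch(ax$entity_type, class = "Term", object_property = "Typedef",
                  NA_character_))
  }
  # OBO tag values carry no language tags or datatypes; only plain
  # literals (and boolean true for is_obsolete) survive a round trip
  plain <- function(v) {
    is_literal(v) && is.null(v$lang) && is.null(v$datatype)
  }
  if (ax$type == "annotation") {
    p <- ax$property
    if (p == props$definition) {
      ok <- all(vapply(ax$anns, function(a)
        a$property == props$xref && plain(a$value), logical(1)))
      return(if (ok && plain(ax$value)) "def" else NA_character_)
    }
    if (length(ax$anns)) return(NA_character_)
    if (p == props$label) return(if (plain(ax$value)) "name" else NA_character_)
    if (p == props$subset) return(if (plain(ax$value)) "subset" else NA_character_)
    if (p == props$xref) return(if (plain(ax$value)) "xref" else NA_character_)
    if (p == props$deprecated) {
      ok <- is_literal(ax$value) && ax$value$value == "true" &&
        identical(ax$value$datatype, XSD_BOOLEAN)
      return(if (ok) "is_obsolete" else NA_character_)
    }
    if (p == props$replaced_by) {
      return(if (is.character(ax$value)) "replaced_by" else NA_character_)
    }
    return(NA_character_)
  }
  if (ax$type == "subclass") {
    if (length(ax$anns) || !is_named_ce(ax$sub)) return(NA_character_)
    if (is_named_ce(ax$sup)) return("is_a")
    if (ax$sup$kind == "some" && is_named_ce(ax$sup$filler)) {
      return("relationship")
    }
    return(NA_character_)
  }
  if (ax$type == "equivalent") {
    if (length(ax$anns) || length(ax$members) != 2) return(NA_character_)
    named <- vapply(ax$members, is_named_ce, logical(1))
    if (all(named)) return("equivalent_to")
    if (sum(named) == 1) {
      expr <- ax$members[[which(!named)]]
      ops <- if (expr$kind == "and") expr$operands else list(expr)
      ok <- all(vapply(ops, function(op) {
        is_named_ce(op) || (op$kind == "some" && is_named_ce(op$filler))
      }, logical(1)))
      if (ok && length(ops) >= 2) return("intersection_of")
    }
    return(NA_character_)
  }
  NA_character_
}

#' Which axioms of a document can be written in OBO format?
#'
#' @param doc an ontology document.
#' @param props annotation-property configuration, see [obo_properties()].
#' @return Logical vector parallel to `doc$axioms`.
#' @export
obo_expressible <- function(doc, props = obo_properties()) {
  vapply(doc$axioms, function(ax) !is.na(obo_axiom_tag(ax, props)), logical(1))
}

obo_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x
}

obo_unescape <- function(x) {
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

#' Serialize a document as OBO flat-file text
#'
#' @param doc an ontology document.
#' @param props annotation-property configuration.
#' @param lossy if `TRUE`, silently restrict to the OBO-expressible subset;
#'   if `FALSE` (default), non-expressible axioms raise a conversion error
#'   listing them.
#' @return Character scalar of OBO text.
#' @export
write_obo_text <- function(doc, props = obo_properties(), lossy = FALSE) {
  expressible <- obo_expressible(doc, props)
  if (!lossy && !all(expressible)) {
    bad <- vapply(doc$axioms[!expressible], axiom_key, character(1))
    owlet_stop("owlet_conversion_error",
      sprintf("%d axiom(s) are not expressible in OBO format:\n  %s",
              sum(!expressible), paste(utils::head(bad, 20), collapse = "\n  ")),
      list(axioms = bad))
  }
  axs <- doc$axioms[expressible]
  pfx <- doc$prefixes
  id_of <- function(iri) obo_id(iri, pfx)

  stanzas <- new.env(parent = emptyenv())  # id -> list(kind, tags)
  ensure <- function(iri, kind) {
    id <- id_of(iri)
    key <- paste0(kind, "\r", id)
    if (is.null(stanzas[[key]])) {
      stanzas[[key]] <- list(kind = kind, id = id, tags = character(0))
    }
    key
  }
  add_tag <- function(key, line) {
    st <- stanzas[[key]]
    st$tags <- c(st$tags, line)
    stanzas[[key]] <- st
  }
  # Typed entity census (declarations define stanza kinds; other axioms
  # attach to Term stanzas, the only place the expressible tags live).
  for (ax in axs) {
    if (ax$type == "declaration") {
      ensure(ax$entity, if (ax$entity_type == "class") "Term" else "Typedef")
    }
  }
  subject_of <- function(ax) {
    switch(ax$type,
      annotation = ax$subject,
      subclass = ax$sub$iri,
      equivalent = {
        named <- vapply(ax$members, is_named_ce, logical(1))
        if (all(named)) ax$members[[1]]$iri else ax$members[[which(named)]]$iri
      })
  }
  for (ax in axs) {
    if (ax$type == "declaration") next
    subj <- subject_of(ax)
    tkey <- paste0("Term\r", id_of(subj))
    pkey <- paste0("Typedef\r", id_of(subj))
    key <- if (!is.null(stanzas[[pkey]])) pkey else ensure(subj, "Term")
    tag <- obo_axiom_tag(ax, props)
    line <- switch(tag,
      name = sprintf("name: %s", lit_value(ax$value)),
      def = {
        xrefs <- sort(vapply(ax$anns, function(a) lit_value(a$value),
                             character(1)))
        sprintf("def: \"%s\" [%s]", obo_escape(lit_value(ax$value)),
                paste(xrefs, collapse = ", "))
      },
      subset = sprintf("subset: %s", lit_value(ax$value)),
      xref = sprintf("xref: %s", lit_value(ax$value)),
      is_obsolete = sprintf("is_obsolete: %s", lit_value(ax$value)),
      replaced_by = sprintf("replaced_by: %s", id_of(lit_value(ax$value))),
      is_a = sprintf("is_a: %s", id_of(ax$sup$iri)),
      relationship = sprintf("relationship: %s %s", id_of(ax$sup$property),
                             id_of(ax$sup$filler$iri)),
      equivalent_to = sprintf("equivalent_to: %s", id_of(ax$members[[2]]$iri)),
      intersection_of = {
        named <- vapply(ax$members, is_named_ce, logical(1))
        expr <- ax$members[[which(!named)]]
        ops <- if (expr$kind == "and") expr$operands else list(expr)
        paste(vapply(ops, function(op) {
          if (is_named_ce(op)) sprintf("intersection_of: %s", id_of(op$iri))
          else sprintf("intersection_of: %s %s", id_of(op$property),
                       id_of(op$filler$iri))
        }, character(1)), collapse = "\n")
      })
    add_tag(key, line)
  }

  tag_rank <- c(name = 1, def = 2, subset = 3, xref = 4, is_a = 5,
                intersection_of = 6, equivalent_to = 7, relationship = 8,
                is_obsolete = 9, replaced_by = 10)
  render_stanza <- function(st) {
    tags <- st$tags
    ranks <- vapply(strsplit(tags, ":"), function(x) {
      r <- tag_rank[[sub(" .*$", "", x[1])]]
      if (is.null(r)) 99 else r
    }, numeric(1))
    tags <- tags[order(ranks, tags)]
    paste(c(sprintf("[%s]", st$kind), sprintf("id: %s", st$id), tags),
          collapse = "\n")
  }

  keys <- sort(ls(stanzas))
  terms <- keys[startsWith(keys, "Term\r")]
  typedefs <- keys[startsWith(keys, "Typedef\r")]
  term_ids <- sub("^Term\r", "", terms)
  typedef_ids <- sub("^Typedef\r", "", typedefs)
  terms <- terms[order(term_ids)]
  typedefs <- typedefs[order(typedef_ids)]

  header <- c("format-version: 1.4")
  if (!is.null(doc$version_iri)) {
    header <- c(header, sprintf("data-version: %s", doc$version_iri))
  }
  if (!is.null(doc$ontology_iri)) {
    oid <- doc$ontology_iri
    m <- regmatches(oid, regexec(paste0("^", NS_OBO, "([A-Za-z0-9_-]+)\\.owl$"),
                                 oid))[[1]]
    header <- c(header, sprintf("ontology: %s",
                                if (length(m) == 2) m[2] else oid))
  }
  custom <- doc$prefixes[!(names(doc$prefixes) %in% names(default_prefixes()))]
  for (nm in sort(names(custom))) {
    header <- c(header, sprintf("idspace: %s %s", nm, custom[[nm]]))
  }
  blocks <- c(paste(header, collapse = "\n"),
              vapply(c(terms, typedefs), function(k)
                render_stanza(stanzas[[k]]), character(1)))
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' Parse OBO flat-file text into a document
#'
#' @param text OBO document text.
#' @param props annotation-property configuration.
#' @return An ontology document.
#' @export
read_obo_text <- function(text, props = obo_properties()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", lines)
  # Strip OBO line comments (" ! ..." trailers handled per-tag).
  stanza_starts <- grep("^\\[.*\\]\\s*$", lines)
  header_lines <- lines[seq_len(if (length(stanza_starts))
    stanza_starts[1] - 1L else length(lines))]

  prefixes <- character(0)
  ontology_iri <- NULL; version_iri <- NULL
  for (ln in header_lines) {
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([A-Za-z_-]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) {
      owlet_stop("owlet_parse_error",
                 sprintf("obo: malformed header line: %s", ln))
    }
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "format-version") next
    if (tag == "data-version") { version_iri <- val; next }
    if (tag == "ontology") {
      ontology_iri <- if (grepl("://", val)) val
                      else paste0(NS_OBO, val, ".owl")
      next
    }
    if (tag == "idspace") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2) prefixes[parts[1]] <- parts[2]
      next
    }
    if (tag %in% c("remark", "date", "saved-by", "auto-generated-by",
                   "default-namespace", "subsetdef", "synonymtypedef")) next
    owlet_stop("owlet_unsupported_axiom",
               sprintf("obo: unsupported header tag '%s'", tag))
  }
  if (!is.null(version_iri) && !grepl("://", version_iri) &&
      !is.null(ontology_iri)) {
    version_iri <- sub("\\.owl$", paste0("/", version_iri, ".owl"),
                       ontology_iri)
  }

  pfx <- default_prefixes()
  if (length(prefixes)) pfx[names(prefixes)] <- unname(prefixes)
  eid <- function(id) obo_expand_id(id, pfx)
  strip_comment <- function(x) trimws(sub("\\s!\\s.*$", "", x))

  axioms <- list()
  add <- function(ax) axioms[[length(axioms) + 1L]] <<- ax

  idx <- c(stanza_starts, length(lines) + 1L)
  for (k in seq_along(stanza_starts)) {
    kind <- sub("^\\[(.*)\\]\\s*$", "\\1", lines[stanza_starts[k]])
    body <- lines[(stanza_starts[k] + 1L):(idx[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (!(kind %in% c("Term", "Typedef"))) {
      owlet_stop("owlet_unsupported_axiom",
                 sprintf("obo: unsupported stanza type [%s]", kind))
    }
    tags <- lapply(body, function(ln) {
      m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(m) != 3) {
        owlet_stop("owlet_parse_error",
                   sprintf("obo: malformed tag line: %s", ln))
      }
      list(tag = m[2], value = m[3])
    })
    tagnames <- vapply(tags, `[[`, character(1), "tag")
    if (!("id" %in% tagnames)) {
      owlet_stop("owlet_parse_error", "obo: stanza without id tag")
    }
    iri <- eid(strip_comment(tags[[which(tagnames == "id")[1]]]$value))
    add(ax_declaration(iri, if (kind == "Term") "class" else "object_property"))
    intersections <- list()
    for (t in tags) {
      v <- t$value
      switch(t$tag,
        id = NULL,
        name = add(ax_annotation(iri, props$label, literal(trimws(v)))),
        def = {
          m <- regmatches(v, regexec(
            "^\"((?:[^\"\\\\]|\\\\.)*)\"\\s*(\\[(.*)\\])?\\s*$", v))[[1]]
          if (length(m) < 2) {
            owlet_stop("owlet_parse_error",
                       sprintf("obo: malformed def line: %s", v))
          }
          xrefs <- if (length(m) >= 4 && nzchar(m[4])) {
            trimws(strsplit(m[4], ",")[[1]])
          } else character(0)
          anns <- lapply(xrefs[nzchar(xrefs)], function(x)
            annotation_pair(props$xref, literal(x)))
          add(ax_annotation(iri, props$definition,
                            literal(obo_unescape(m[2])), anns))
        },
        subset = add(ax_annotation(iri, props$subset,
                                   literal(strip_comment(v)))),
        xref = add(ax_annotation(iri, props$xref,
                                 literal(sub("\\s+\".*\"\\s*$", "", trimws(v))))),
        is_a = add(ax_subclass(ce_named(iri), ce_named(eid(strip_comment(v))))),
        relationship = {
          parts <- strsplit(strip_comment(v), "\\s+")[[1]]
          if (length(parts) != 2) {
            owlet_stop("owlet_parse_error",
                       sprintf("obo: malformed relationship line: %s", v))
          }
          add(ax_subclass(ce_named(iri),
                          ce_some(eid(parts[1]), ce_named(eid(parts[2])))))
        },
        equivalent_to = add(ax_equivalent(list(ce_named(iri),
                                               ce_named(eid(strip_comment(v)))))),
        intersection_of = {
          parts <- strsplit(strip_comment(v), "\\s+")[[1]]
          intersections[[length(intersections) + 1L]] <-
            if (length(parts) == 1) ce_named(eid(parts[1]))
            else ce_some(eid(parts[1]), ce_named(eid(parts[2])))
        },
        is_obsolete = {
          if (trimws(strip_comment(v)) == "true") {
            add(ax_annotation(iri, props$deprecated,
                              literal("true", datatype = XSD_BOOLEAN)))
          }
        },
        replaced_by = add(ax_annotation(iri, props$replaced_by,
                                        eid(strip_comment(v)))),
        owlet_stop("owlet_unsupported_axiom",
                   sprintf("obo: unsupported tag '%s' in [%s] stanza",
                           t$tag, kind))
      )
    }
    if (length(intersections)) {
      if (length(intersections) < 2) {
        owlet_stop("owlet_parse_error",
                   "obo: intersection_of requires at least two clauses")
      }
      add(ax_equivalent(list(ce_named(iri), ce_and(intersections))))
    }
  }
  ontology_document(ontology_iri = ontology_iri, version_iri = version_iri,
                    prefixes = prefixes, axioms = axioms)
}
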