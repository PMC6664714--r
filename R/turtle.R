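# Turtle serialization and parsing.
#
# The writer is a pure function of the document: prefixes sorted by name,
# axioms pre-sorted, blank nodes labelled in emission order, subjects
# grouped by first appearance.  Writing the same document twice yields
# byte-identical files.
#
# The parser covers the Turtle constructs the OWL mapping needs: prefix
# directives, IRIs, prefixed names, blank-node labels and property lists
# ([ ... ]), collections, string literals with language tags and
# datatypes, numeric and boolean shorthand, object/predicate lists.

escape_turtle_string <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\r", "\\\\r", x)
  x <- gsub("\t", "\\\\t", x)
  x
}

unescape_turtle_string <- function(x) {
  out <- character(1)
  chars <- strsplit(x, "")[[1]]
  res <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      nxt <- chars[i + 1L]
      res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                           "\"" = "\"", "\\" = "\\", nxt))
      i <- i + 2L
    } else {
      res <- c(res, ch)
      i <- i + 1L
    }
  }
  paste(res, collapse = "")
}

render_term <- function(value, kind, lang, dt, prefixes) {
  if (kind == "bnode") return(value)
  if (kind == "iri") {
    c <- contract_iri(value, prefixes)
    return(if (c == value) paste0("<", value, ">") else c)
  }
  lit <- paste0("\"", escape_turtle_string(value), "\"")
  if (!is.na(lang)) return(paste0(lit, "@", lang))
  if (!is.na(dt)) {
    cdt <- contract_iri(dt, prefixes)
    return(paste0(lit, "^^", if (cdt == dt) paste0("<", dt, ">") else cdt))
  }
  lit
}

#' Serialize triples as Turtle text
#'
#' @param triples triple data.frame.
#' @param prefixes named character vector of prefixes to declare.
#' @return A single character scalar of Turtle text.
#' @export
triples_to_turtle <- function(triples, prefixes) {
  lines <- character(0)
  for (nm in sort(names(prefixes))) {
    lines <- c(lines, sprintf("@prefix %s: <%s> .", nm, prefixes[[nm]]))
  }
  if (length(lines)) lines <- c(lines, "")
  subjects <- unique(triples$s)
  for (subj in subjects) {
    rows <- triples[triples$s == subj, , drop = FALSE]
    skind <- rows$s_kind[1]
    sterm <- render_term(subj, skind, NA, NA, prefixes)
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      pterm <- if (rows$p[i] == RDF_TYPE) "a"
               else render_term(rows$p[i], "iri", NA, NA, prefixes)
      oterm <- render_term(rows$o[i], rows$o_kind[i], rows$lang[i],
                           rows$dt[i], prefixes)
      paste(pterm, oterm)
    }, character(1))
    indent <- strrep(" ", nchar(sterm) + 1L)
    body <- paste(parts, collapse = paste0(" ;\n", indent))
    lines <- c(lines, paste0(sterm, " ", body, " ."))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# ---- Tokenizer -------------------------------------------------------------

turtle_tokens <- function(text) {
  tokens <- list()
  n <- nchar(text)
  i <- 1L
  line <- 1L
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           line = line)
  }
  substr_at <- function(from, len) substr(text, from, from + len - 1L)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
      next
    }
    rest <- substr(text, i, n)
    if (ch == "<") {
      m <- regmatches(rest, regexpr("^<[^>]*>", rest))
      if (!length(m)) owlet_stop("owlet_parse_error",
        sprintf("turtle: unterminated IRI at line %d", line))
      push("iri", substr(m, 2, nchar(m) - 1L))
      i <- i + nchar(m); next
    }
    if (ch == "\"") {
      m <- regmatches(rest, regexpr('^"([^"\\\\]|\\\\.)*"', rest))
      if (!length(m)) owlet_stop("owlet_parse_error",
        sprintf("turtle: unterminated string at line %d", line))
      push("string", unescape_turtle_string(substr(m, 2, nchar(m) - 1L)))
      i <- i + nchar(m); next
    }
    if (substr_at(i, 2) == "^^") { push("dtsep", "^^"); i <- i + 2L; next }
    if (ch == "@") {
      m <- regmatches(rest, regexpr("^@[A-Za-z][A-Za-z0-9-]*", rest))
      word <- substring(m, 2)
      if (word %in% c("prefix", "base")) push("directive", word)
      else push("lang", word)
      i <- i + nchar(m); next
    }
    if (substr_at(i, 2) == "_:") {
      m <- regmatches(rest, regexpr("^_:[A-Za-z0-9_]+", rest))
      push("bnode_label", m)
      i <- i + nchar(m); next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(ch, ch); i <- i + 1L; next
    }
    m <- regmatches(rest, regexpr(
      "^([A-Za-z_][A-Za-z0-9_.-]*)?:([A-Za-z0-9_%-]([A-Za-z0-9_.%-]*[A-Za-z0-9_%-])?)?",
      rest))
    if (length(m) && nchar(m) > 0 && grepl(":", m)) {
      push("pname", m); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[+-]?[0-9]+(\\.[0-9]+)?", rest))
    if (length(m) && nchar(m)) {
      push("number", m); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9]*", rest))
    if (length(m) && nchar(m)) {
      if (m == "a") push("a", "a")
      else if (m %in% c("true", "false")) push("boolean", m)
      else if (toupper(m) %in% c("PREFIX", "BASE")) {
        push("directive", tolower(m))
      } else {
        owlet_stop("owlet_parse_error",
          sprintf("turtle: unexpected token '%s' at line %d", m, line))
      }
      i <- i + nchar(m); next
    }
    owlet_stop("owlet_parse_error",
      sprintf("turtle: unexpected character '%s' at line %d", ch, line))
  }
  tokens
}

# ---- Parser ----------------------------------------------------------------

#' Parse Turtle text into triples
#'
#' @param text Turtle document text.
#' @return A list with `triples` (data.frame) and `prefixes` (named
#'   character vector).
#' @export
parse_turtle <- function(text) {
  toks <- turtle_tokens(text)
  sink <- new_triple_sink()
  prefixes <- character(0)
  pos <- 1L
  n <- length(toks)

  peek <- function() if (pos <= n) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) {
      owlet_stop("owlet_parse_error",
        sprintf("turtle: expected '%s' at line %s", type,
                if (is.null(t)) "end of input" else t$line))
    }
    advance()
  }
  expand_pname <- function(pn, ln) {
    m <- regmatches(pn, regexec("^([^:]*):(.*)$", pn))[[1]]
    pfx <- m[2]; local <- m[3]
    if (!(pfx %in% names(prefixes))) {
      owlet_stop("owlet_parse_error",
        sprintf("turtle: undeclared prefix '%s:' at line %d", pfx, ln))
    }
    paste0(prefixes[[pfx]], local)
  }
  fresh_bnode <- function() {
    sink$bcount <- sink$bcount + 1L
    sprintf("_:g%d", sink$bcount)
  }
  emit <- function(s, s_kind, p, o) {
    sink_emit(sink, s, s_kind, p, o$value, o$kind, o$lang, o$dt)
  }
  node <- function(value, kind, lang = NA_character_, dt = NA_character_) {
    list(value = value, kind = kind, lang = lang, dt = dt)
  }

  parse_object <- function() {
    t <- peek()
    if (is.null(t)) owlet_stop("owlet_parse_error",
                               "turtle: unexpected end of input")
    if (t$type == "iri") { advance(); return(node(t$value, "iri")) }
    if (t$type == "pname") {
      advance(); return(node(expand_pname(t$value, t$line), "iri"))
    }
    if (t$type == "bnode_label") {
      advance(); return(node(paste0("_:p", substring(t$value, 3)), "bnode"))
    }
    if (t$type == "string") {
      advance()
      nx <- peek()
      if (!is.null(nx) && nx$type == "lang") {
        advance(); return(node(t$value, "literal", lang = nx$value))
      }
      if (!is.null(nx) && nx$type == "dtsep") {
        advance()
        dt_t <- advance()
        dt <- if (dt_t$type == "iri") dt_t$value
              else if (dt_t$type == "pname") expand_pname(dt_t$value, dt_t$line)
              else owlet_stop("owlet_parse_error",
                sprintf("turtle: bad datatype at line %d", dt_t$line))
        return(node(t$value, "literal", dt = dt))
      }
      return(node(t$value, "literal"))
    }
    if (t$type == "number") {
      advance()
      dt <- if (grepl("\\.", t$value)) paste0(NS_XSD, "decimal")
            else paste0(NS_XSD, "integer")
      return(node(t$value, "literal", dt = dt))
    }
    if (t$type == "boolean") {
      advance(); return(node(t$value, "literal", dt = XSD_BOOLEAN))
    }
    if (t$type == "[") {
      advance()
      b <- fresh_bnode()
      if (!is.null(peek()) && peek()$type != "]") {
        parse_predicate_object_list(b, "bnode")
      }
      expect("]")
      return(node(b, "bnode"))
    }
    if (t$type == "(") {
      advance()
      items <- list()
      while (!is.null(peek()) && peek()$type != ")") {
        items[[length(items) + 1L]] <- parse_object()
      }
      expect(")")
      if (!length(items)) return(node(RDF_NIL, "iri"))
      head <- fresh_bnode()
      cur <- head
      for (i in seq_along(items)) {
        emit(cur, "bnode", RDF_FIRST, items[[i]])
        if (i < length(items)) {
          nxt <- fresh_bnode()
          emit(cur, "bnode", RDF_REST, node(nxt, "bnode"))
          cur <- nxt
        } else {
          emit(cur, "bnode", RDF_REST, node(RDF_NIL, "iri"))
        }
      }
      return(node(head, "bnode"))
    }
    owlet_stop("owlet_parse_error",
      sprintf("turtle: unexpected '%s' at line %d", t$type, t$line))
  }

  parse_predicate_object_list <- function(s, s_kind) {
    repeat {
      t <- peek()
      if (is.null(t)) break
      if (t$type %in% c(";", ".", "]")) {
        if (t$type == ";") { advance(); next } else break
      }
      p <- if (t$type == "a") { advance(); RDF_TYPE }
           else if (t$type == "iri") { advance(); t$value }
           else if (t$type == "pname") { advance(); expand_pname(t$value, t$line) }
           else owlet_stop("owlet_parse_error",
             sprintf("turtle: expected predicate at line %d", t$line))
      repeat {
        emit(s, s_kind, p, parse_object())
        if (!is.null(peek()) && peek()$type == ",") advance() else break
      }
      if (!is.null(peek()) && peek()$type == ";") { advance() } else break
    }
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "directive") {
      advance()
      if (t$value == "prefix") {
        pn <- expect("pname")
        iri <- expect("iri")
        pfx <- sub(":$", "", pn$value)
        prefixes[pfx] <- iri$value
        if (!is.null(peek()) && peek()$type == ".") advance()
      } else { # base — accepted, unused (documents use absolute IRIs)
        expect("iri")
        if (!is.null(peek()) && peek()$type == ".") advance()
      }
      next
    }
    subj <- parse_object()
    if (subj$kind == "literal") {
      owlet_stop("owlet_parse_error", "turtle: literal subject")
    }
    parse_predicate_object_list(subj$value, subj$kind)
    expect(".")
  }
  list(triples = sink_frame(sink), prefixes = prefixes)
}
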