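# Synthetic test-ontology generator with known ground truth.
#
# A fixture is a rooted DAG taxonomy (each class picks 1-2 parents among
# earlier classes, guaranteeing acyclicity and a single root) with unique
# labels and period-terminated definitions, genus-differentia equivalence
# axioms ("G and (R some C)") on a configurable fraction of classes, an
# optional chain of imported documents, and an exactly-known census of
# injected QC violations.  The accompanying ledger is computed by
# independent simple algorithms — graph reachability for MIREOT
# expectations and an exhaustive expression-level closure for entailments
# — never by the reasoner or extractor under test.
#
# Generation is reproducible: a single integer seed drives R's
# Mersenne-Twister generator (kind pinned explicitly), and the serialized
# fixture is byte-identical across runs and platforms.

FX_NS <- "http://example.org/fx/"

#' Specify a synthetic fixture
#'
#' @param n_classes number of classes in the main taxonomy (>= 2).
#' @param n_properties number of object properties.
#' @param p_existential probability that a class (beyond the first two)
#'   carries a genus-differentia equivalence definition.
#' @param violation_census named list/vector mapping default-profile rule
#'   names to injected violation counts.
#' @param import_depth length of the chain of imported documents.
#' @param n_unsatisfiable number of injected unsatisfiable classes (each
#'   adds a fresh disjointness clash).
#' @param n_duplicate_axioms number of subclass edges duplicated with
#'   differing axiom annotations.
#' @param n_deprecated number of classes marked deprecated with a
#'   replacement annotation.
#' @param seed integer seed.
#' @return A validated spec of class `owlet_fixture_spec`.
#' @export
fixture_spec <- function(n_classes = 20, n_properties = 3,
                         p_existential = 0.2,
                         violation_census = list(), import_depth = 0,
                         n_unsatisfiable = 0, n_duplicate_axioms = 0,
                         n_deprecated = 0, seed = 1) {
  stopifnot(n_classes >= 2, n_properties >= 0,
            p_existential >= 0, p_existential <= 1,
            import_depth >= 0, n_unsatisfiable >= 0,
            n_duplicate_axioms >= 0, n_deprecated >= 0)
  census <- as.list(violation_census)
  known_rules <- c("missing_label", "duplicate_label", "duplicate_definition",
                   "multiple_definitions", "self_reference",
                   "trailing_whitespace", "invalid_xref_syntax",
                   "missing_ontology_license", "missing_ontology_title",
                   "definition_format", "missing_definition",
                   "equivalent_class_pair")
  unknown <- setdiff(names(census), known_rules)
  if (length(unknown)) {
    owlet_stop("owlet_spec_error",
      sprintf("unknown violation rule(s) in census: %s",
              paste(unknown, collapse = ", ")))
  }
  for (r in c("missing_ontology_license", "missing_ontology_title")) {
    if (!is.null(census[[r]]) && census[[r]] > 1) {
      owlet_stop("owlet_spec_error",
                 sprintf("census for %s can be at most 1", r))
    }
  }
  if (!is.null(census$duplicate_label) && census$duplicate_label == 1) {
    owlet_stop("owlet_spec_error",
               "duplicate_label census needs at least 2 (a shared label)")
  }
  if (!is.null(census$duplicate_definition) &&
      census$duplicate_definition == 1) {
    owlet_stop("owlet_spec_error",
               "duplicate_definition census needs at least 2")
  }
  structure(list(n_classes = n_classes, n_properties = n_properties,
                 p_existential = p_existential, violation_census = census,
                 import_depth = import_depth,
                 n_unsatisfiable = n_unsatisfiable,
                 n_duplicate_axioms = n_duplicate_axioms,
                 n_deprecated = n_deprecated, seed = seed),
            class = "owlet_fixture_spec")
}

fx_class <- function(i) sprintf("%sC%04d", FX_NS, i)
fx_prop <- function(i) sprintf("%sP%d", FX_NS, i)

with_fixture_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Generate a synthetic fixture ontology with its ground-truth ledger
#'
#' @param spec an `owlet_fixture_spec`.
#' @param props annotation-property configuration.
#' @return A list of class `owlet_fixture`: `doc` (the main document),
#'   `imports` (list of import documents keyed by IRI), and `ledger`
#'   (ground truth: entities, asserted and expected inferred edges,
#'   entailed subsumption closure, unsatisfiable classes, injected
#'   violation census with subjects, MIREOT expectation, designated
#'   module seed).
#' @export
generate_fixture <- function(spec, props = obo_properties()) {
  with_fixture_rng(spec$seed, generate_fixture_impl(spec, props))
}

generate_fixture_impl <- function(spec, props) {
  n <- spec$n_classes
  classes <- vapply(seq_len(n), fx_class, character(1))
  properties <- if (spec$n_properties) {
    vapply(seq_len(spec$n_properties), fx_prop, character(1))
  } else character(0)

  # --- taxonomy DAG ---------------------------------------------------------
  edges_sub <- character(0); edges_sup <- character(0)
  for (i in 2:n) {
    k <- if (i > 2 && stats::runif(1) < 0.3) 2L else 1L
    parents <- sample.int(i - 1L, min(k, i - 1L))
    for (p in parents) {
      edges_sub <- c(edges_sub, classes[i]); edges_sup <- c(edges_sup, classes[p])
    }
  }

  labels <- stats::setNames(sprintf("fixture term %d", seq_len(n)), classes)
  defs <- stats::setNames(
    sprintf("A synthetic definition of fixture term %d.", seq_len(n)), classes)

  # --- genus-differentia equivalence definitions ---------------------------
  # each definition uses a fresh (genus, property, filler) combination
  equiv_defs <- list()   # class -> list(genus, prop, filler)
  if (spec$n_properties && spec$p_existential > 0 && n >= 3) {
    used_combo <- character(0)
    for (i in 3:n) {
      if (stats::runif(1) >= spec$p_existential) next
      genus <- edges_sup[match(classes[i], edges_sub)]
      prop <- properties[sample.int(length(properties), 1)]
      filler_pool <- setdiff(classes[seq_len(i - 1L)], genus)
      if (!length(filler_pool)) next
      filler <- filler_pool[sample.int(length(filler_pool), 1)]
      combo <- paste(genus, prop, filler)
      if (combo %in% used_combo) next
      used_combo <- c(used_combo, combo)
      equiv_defs[[classes[i]]] <- list(genus = genus, prop = prop,
                                       filler = filler)
    }
  }

  build_logical <- function() {
    axs <- list()
    for (j in seq_along(edges_sub)) {
      axs[[length(axs) + 1L]] <- ax_subclass(edges_sub[j], edges_sup[j])
    }
    for (cls in names(equiv_defs)) {
      d <- equiv_defs[[cls]]
      axs[[length(axs) + 1L]] <- ax_equivalent(list(
        ce_named(cls),
        ce_and(list(ce_named(d$genus), ce_some(d$prop, ce_named(d$filler))))))
    }
    axs
  }

  # drop definitions that would make two distinct classes inferred
  # equivalent by accident (would corrupt the violation census)
  repeat {
    closure <- naive_entailed_subsumptions(
      ontology_document(axioms = build_logical()))
    pairs <- closure$subsumptions
    mutual <- merge(pairs, stats::setNames(pairs, c("sup", "sub")),
                    by = c("sub", "sup"))
    mutual <- mutual[mutual$sub < mutual$sup, , drop = FALSE]
    if (!nrow(mutual)) break
    offender <- max(c(mutual$sub, mutual$sup))
    if (!(offender %in% names(equiv_defs))) {
      offender <- intersect(names(equiv_defs),
                            unique(c(mutual$sub, mutual$sup)))
      if (!length(offender)) break
      offender <- max(offender)
    }
    equiv_defs[[offender]] <- NULL
  }

  # --- violation injection --------------------------------------------------
  census <- spec$violation_census
  class_level_rules <- c("missing_label", "duplicate_label",
                         "duplicate_definition", "multiple_definitions",
                         "self_reference", "trailing_whitespace",
                         "invalid_xref_syntax", "definition_format",
                         "missing_definition")
  need <- sum(unlist(census[intersect(names(census), class_level_rules)])) +
    2L * (census$equivalent_class_pair %||% 0L) +
    spec$n_duplicate_axioms + spec$n_deprecated
  pool <- sample(classes[-1])   # root excluded, deterministic shuffle
  if (need > length(pool)) {
    owlet_stop("owlet_spec_error",
      sprintf("infeasible violation census: %d victims needed, %d available",
              need, length(pool)))
  }
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  victims <- list()
  for (rule in sort(intersect(names(census), class_level_rules))) {
    victims[[rule]] <- take(census[[rule]])
  }
  eq_pairs <- NULL
  if ((census$equivalent_class_pair %||% 0L) > 0) {
    # equating comparable classes (or pairs that chain through the DAG)
    # would collapse whole node groups and inflate the census; each
    # candidate pair is validated against the closure including the pairs
    # already selected, so the injected pairs are exactly the inferred
    # equivalences
    mutual_pairs <- function(pairs) {
      eqaxs <- lapply(pairs, function(pr)
        ax_equivalent(list(ce_named(pr[1]), ce_named(pr[2]))))
      cl <- naive_entailed_subsumptions(
        ontology_document(axioms = c(build_logical(), eqaxs)))$subsumptions
      fwd <- paste(cl$sub, cl$sup)
      rev <- paste(cl$sup, cl$sub)
      mut <- cl[fwd %in% rev & cl$sub < cl$sup, , drop = FALSE]
      sort(paste(mut$sub, mut$sup))
    }
    sel_pairs <- list()
    for (k in seq_len(census$equivalent_class_pair)) {
      found <- FALSE
      for (i in seq_along(pool)) {
        for (j in seq_along(pool)) {
          if (j <= i) next
          cand <- c(sel_pairs, list(sort(pool[c(i, j)])))
          expected <- sort(vapply(cand, paste, character(1), collapse = " "))
          if (identical(mutual_pairs(cand), expected)) {
            sel_pairs <- cand
            pool <- pool[-c(i, j)]
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) {
        owlet_stop("owlet_spec_error",
          "infeasible census: no independent class pair left for equivalent_class_pair")
      }
    }
    eq_pairs <- do.call(rbind, sel_pairs)
    victims$equivalent_class_pair <- apply(eq_pairs, 1, function(r)
      paste(sort(r), collapse = " "))
  }
  dup_victims <- if (spec$n_duplicate_axioms) take(spec$n_duplicate_axioms)
                 else character(0)
  depr_victims <- if (spec$n_deprecated) take(spec$n_deprecated)
                  else character(0)

  # label/definition adjustments
  for (v in victims$missing_label %||% character(0)) labels[v] <- NA
  for (v in victims$duplicate_label %||% character(0)) {
    labels[v] <- "duplicated fixture label"
  }
  for (v in victims$trailing_whitespace %||% character(0)) {
    labels[v] <- paste0(labels[v], " ")
  }
  for (v in victims$missing_definition %||% character(0)) defs[v] <- NA
  for (v in victims$duplicate_definition %||% character(0)) {
    defs[v] <- "A duplicated synthetic definition."
  }
  for (v in victims$definition_format %||% character(0)) {
    defs[v] <- sprintf("unformatted definition of %s without a period",
                       basename(v))
  }

  # --- assemble axioms ------------------------------------------------------
  axioms <- list()
  add <- function(ax) axioms[[length(axioms) + 1L]] <<- ax
  for (cls in classes) add(ax_declaration(cls, "class"))
  for (p in properties) add(ax_declaration(p, "object_property"))
  for (cls in classes) {
    if (!is.na(labels[cls])) {
      add(ax_annotation(cls, props$label, literal(unname(labels[cls]))))
    }
    if (!is.na(defs[cls])) {
      add(ax_annotation(cls, props$definition, literal(unname(defs[cls]))))
    }
  }
  logical_axioms <- build_logical()
  dup_keys <- if (length(dup_victims)) {
    vapply(dup_victims, function(v) {
      sup <- edges_sup[match(v, edges_sub)]
      logical_key(ax_subclass(v, sup))
    }, character(1))
  } else character(0)
  for (ax in logical_axioms) {
    if (logical_key(ax) %in% dup_keys) {
      add(ax_subclass(ax$sub, ax$sup, anns = list(
        annotation_pair(paste0(NS_RDFS, "comment"), literal("copy one")))))
      add(ax_subclass(ax$sub, ax$sup, anns = list(
        annotation_pair(paste0(NS_RDFS, "comment"), literal("copy two")))))
    } else {
      add(ax)
    }
  }
  for (i in seq_along(victims$multiple_definitions %||% character(0))) {
    v <- victims$multiple_definitions[i]
    add(ax_annotation(v, props$definition,
      literal(sprintf("An additional synthetic definition (%d).", i))))
  }
  for (v in victims$self_reference %||% character(0)) {
    add(ax_subclass(v, v))
  }
  for (i in seq_along(victims$invalid_xref_syntax %||% character(0))) {
    v <- victims$invalid_xref_syntax[i]
    add(ax_annotation(v, props$xref, literal(sprintf("bad xref %d", i))))
  }
  if (!is.null(eq_pairs)) {
    for (r in seq_len(nrow(eq_pairs))) {
      add(ax_equivalent(list(ce_named(eq_pairs[r, 1]),
                             ce_named(eq_pairs[r, 2]))))
    }
  }
  for (v in depr_victims) {
    parent <- edges_sup[match(v, edges_sub)]
    add(ax_annotation(v, props$deprecated,
                      literal("true", datatype = XSD_BOOLEAN)))
    add(ax_annotation(v, props$replaced_by, parent))
  }
  unsat_classes <- character(0)
  if (spec$n_unsatisfiable) {
    for (i in seq_len(spec$n_unsatisfiable)) {
      x <- sprintf("%sU%04dX", FX_NS, i)
      a <- sprintf("%sU%04dA", FX_NS, i)
      b <- sprintf("%sU%04dB", FX_NS, i)
      unsat_classes <- c(unsat_classes, x)
      for (cls in c(x, a, b)) {
        add(ax_declaration(cls, "class"))
        add(ax_annotation(cls, props$label,
                          literal(sprintf("clash term %s", basename(cls)))))
        add(ax_annotation(cls, props$definition,
          literal(sprintf("A synthetic clash participant %s.", basename(cls)))))
      }
      add(ax_subclass(a, classes[1])); add(ax_subclass(b, classes[1]))
      add(ax_subclass(x, a)); add(ax_subclass(x, b))
      add(ax_disjoint(c(a, b)))
    }
  }

  # --- imports --------------------------------------------------------------
  imports <- list()
  if (spec$import_depth > 0) {
    for (d in seq_len(spec$import_depth)) {
      iri <- sprintf("%simport-%d.owl", FX_NS, d)
      icls <- vapply(1:3, function(j)
        sprintf("%simp%d/C%d", FX_NS, d, j), character(1))
      iaxs <- list()
      for (j in seq_along(icls)) {
        iaxs[[length(iaxs) + 1L]] <- ax_declaration(icls[j], "class")
        iaxs[[length(iaxs) + 1L]] <- ax_annotation(icls[j], props$label,
          literal(sprintf("imported term %d-%d", d, j)))
        if (j > 1) {
          iaxs[[length(iaxs) + 1L]] <- ax_subclass(icls[j], icls[j - 1])
        }
      }
      imports[[iri]] <- ontology_document(
        ontology_iri = iri,
        prefixes = c(FX = FX_NS),
        imports = if (d < spec$import_depth) {
          sprintf("%simport-%d.owl", FX_NS, d + 1)
        } else character(0),
        axioms = iaxs)
    }
  }

  # --- document -------------------------------------------------------------
  onto_ann <- list()
  if ((census$missing_ontology_title %||% 0L) == 0) {
    onto_ann <- c(onto_ann, list(annotation_pair(props$title,
      literal("Synthetic fixture ontology"))))
  }
  if ((census$missing_ontology_license %||% 0L) == 0) {
    onto_ann <- c(onto_ann, list(annotation_pair(props$license,
      "https://creativecommons.org/licenses/by/4.0/")))
  }
  doc <- ontology_document(
    ontology_iri = paste0(FX_NS, "fixture.owl"),
    prefixes = c(FX = FX_NS),
    imports = names(imports)[seq_len(min(1L, length(imports)))],
    axioms = axioms,
    ontology_annotations = onto_ann)

  # --- ledger (independent algorithms) -------------------------------------
  closure <- naive_entailed_subsumptions(doc)
  asserted <- data.frame(sub = edges_sub, sup = edges_sup,
                         stringsAsFactors = FALSE)
  ledger_census <- census
  # designated MIREOT bottom: the last class; expectation via plain BFS
  mireot_bottom <- classes[n]
  keepset <- mireot_bottom
  queue <- mireot_bottom
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    ps <- setdiff(asserted$sup[asserted$sub == x], keepset)
    keepset <- c(keepset, ps)
    queue <- c(queue, ps)
  }
  ledger <- list(
    classes = classes,
    properties = properties,
    annotation_properties_used = unique(c(props$label, props$definition)),
    asserted_edges = asserted,
    subsumptions = closure$subsumptions,
    inferred_direct_edges = closure$direct_edges,
    unsatisfiable = closure$unsatisfiable,
    violation_census = ledger_census,
    violation_subjects = victims,
    duplicate_axiom_subjects = dup_victims,
    deprecated_subjects = depr_victims,
    injected_unsatisfiable = unsat_classes,
    mireot = list(bottom = mireot_bottom, expected_classes = sort(keepset)),
    designated_seed = classes[max(2L, n %/% 2L)]
  )
  structure(list(doc = doc, imports = imports, ledger = ledger,
                 spec = spec), class = "owlet_fixture")
}

#' @export
print.owlet_fixture <- function(x, ...) {
  cat("<owlet_fixture>", length(x$ledger$classes), "classes,",
      nrow(x$ledger$asserted_edges), "asserted edges,",
      length(x$imports), "import(s)\n")
  invisible(x)
}

#' Write a fixture to disk
#'
#' Writes `fixture.ttl` and `fixture.obo` (lossy OBO projection), the
#' import chain, a TSV catalog and `ledger.yaml`.
#'
#' @param fixture an `owlet_fixture`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_document(fixture$doc, file.path(dir, "fixture.ttl"), "turtle")
  write_document(fixture$doc, file.path(dir, "fixture.obo"), "obo",
                 lossy = TRUE)
  cat_lines <- character(0)
  i <- 0L
  for (iri in names(fixture$imports)) {
    i <- i + 1L
    fn <- sprintf("import-%d.ttl", i)
    write_document(fixture$imports[[iri]], file.path(dir, fn), "turtle")
    cat_lines <- c(cat_lines, paste0(iri, "\t", fn))
  }
  writeLines(cat_lines, file.path(dir, "catalog.tsv"))
  led <- fixture$ledger
  led$asserted_edges <- as.list(led$asserted_edges)
  led$subsumptions <- as.list(led$subsumptions)
  led$inferred_direct_edges <- as.list(led$inferred_direct_edges)
  writeLines(yaml::as.yaml(led), file.path(dir, "ledger.yaml"))
  invisible(dir)
}

# ---- independent entailment oracle ----------------------------------------
# Exhaustive closure over the subexpressions occurring in the document.
# Deliberately shares nothing with the saturation reasoner: no normal
# forms, no auxiliary names — plain rule application over expression keys
# to a fixpoint.  Exponential-ish but fine at fixture scale; this is the
# ledger's and the test suite's ground truth.

#' Entailed subsumptions by exhaustive closure (independent oracle)
#'
#' @param doc an ontology document.
#' @return List with `subsumptions` (data.frame `sub`, `sup` over named
#'   classes, non-reflexive), `direct_edges` (transitive reduction over
#'   the equivalence-quotient), `unsatisfiable` (character).
#' @export
naive_entailed_subsumptions <- function(doc) {
  BOT <- "__bot__"
  exprs <- list()
  seen <- character(0)
  note <- function(ce) {
    key <- ce_key(ce)
    if (!(key %in% seen)) {
      seen <<- c(seen, key)
      exprs[[key]] <<- ce
      if (ce$kind == "some") note(ce$filler)
      if (ce$kind == "and") for (op in ce$operands) note(op)
    }
    key
  }
  subs <- list()     # asserted expression-level inclusions
  disj <- list()
  named <- character(0)
  for (ax in doc$axioms) {
    if (ax$type == "subclass") {
      subs[[length(subs) + 1L]] <- c(note(ax$sub), note(ax$sup))
    } else if (ax$type == "equivalent") {
      keys <- vapply(ax$members, note, character(1))
      for (i in seq_along(keys)) for (j in seq_along(keys)) {
        if (i != j) subs[[length(subs) + 1L]] <- c(keys[i], keys[j])
      }
    } else if (ax$type == "disjoint") {
      keys <- vapply(ax$members, function(m) note(ce_named(m)), character(1))
      cmb <- utils::combn(keys, 2)
      for (j in seq_len(ncol(cmb))) {
        disj[[length(disj) + 1L]] <- cmb[, j]
      }
    } else if (ax$type == "declaration" && ax$entity_type == "class") {
      note(ce_named(ax$entity))
    }
  }
  named <- names(Filter(function(e) e$kind == "named", exprs))
  keys <- c(names(exprs), BOT)
  m <- length(keys)
  idx <- stats::setNames(seq_len(m), keys)
  R <- diag(m) > 0
  dimnames(R) <- list(keys, keys)
  R[, BOT] <- FALSE; R[BOT, ] <- TRUE   # Bottom is subsumed by everything
  R[BOT, BOT] <- TRUE
  for (s in subs) R[s[1], s[2]] <- TRUE

  somes <- Filter(function(e) e$kind == "some", exprs)
  ands <- Filter(function(e) e$kind == "and", exprs)
  repeat {
    before <- sum(R)
    # transitivity
    R <- R | ((R * 1) %*% (R * 1) > 0)
    # intersection decomposition / composition
    for (k in names(ands)) {
      opk <- vapply(ands[[k]]$operands, ce_key, character(1))
      for (o in opk) R[k, o] <- TRUE
      hit <- rowSums(R[, opk, drop = FALSE]) == length(opk)
      R[hit, k] <- TRUE
    }
    # existential monotonicity: B [= C => (R some B) [= (R some C)
    sk <- names(somes)
    if (length(sk) > 1) {
      for (a in sk) for (b in sk) {
        if (a == b || R[a, b]) next
        ea <- somes[[a]]; eb <- somes[[b]]
        if (ea$property == eb$property &&
            R[ce_key(ea$filler), ce_key(eb$filler)]) {
          R[a, b] <- TRUE
        }
      }
    }
    # disjointness clash
    for (d in disj) {
      hit <- R[, d[1]] & R[, d[2]]
      R[hit, BOT] <- TRUE
    }
    # (R some Bottom) is Bottom
    for (a in sk) {
      if (R[ce_key(somes[[a]]$filler), BOT]) R[a, BOT] <- TRUE
    }
    # everything subsumed by Bottom is subsumed by everything
    dead <- which(R[, BOT])
    if (length(dead)) R[dead, ] <- TRUE
    if (sum(R) == before) break
  }

  named <- setdiff(named, c(paste0("<", OWL_THING, ">"),
                            paste0("<", OWL_NOTHING, ">")))
  unsat <- named[R[named, BOT]]
  iri_of <- function(k) exprs[[k]]$iri
  pairs <- which(R[named, named, drop = FALSE], arr.ind = TRUE)
  subsumptions <- data.frame(
    sub = vapply(named[pairs[, 1]], iri_of, character(1)),
    sup = vapply(named[pairs[, 2]], iri_of, character(1)),
    stringsAsFactors = FALSE)
  subsumptions <- subsumptions[subsumptions$sub != subsumptions$sup, ,
                               drop = FALSE]
  subsumptions <- unique(subsumptions)
  subsumptions <- subsumptions[order(subsumptions$sub, subsumptions$sup), ,
                               drop = FALSE]
  rownames(subsumptions) <- NULL

  # quotient + transitive reduction among satisfiable classes
  sat_named <- setdiff(named, named[R[named, BOT]])
  iris <- vapply(sat_named, iri_of, character(1))
  Rn <- R[sat_named, sat_named, drop = FALSE]
  dimnames(Rn) <- list(iris, iris)
  groups <- list(); assigned <- character(0)
  for (a in sort(iris)) {
    if (a %in% assigned) next
    members <- sort(iris[Rn[a, iris] & Rn[iris, a]])
    assigned <- c(assigned, members)
    groups[[members[1]]] <- members
  }
  reps <- names(groups)
  direct <- list()
  for (a in reps) for (b in reps) {
    if (a == b || !Rn[a, b]) next
    via <- any(vapply(setdiff(reps, c(a, b)), function(cc)
      Rn[a, cc] && Rn[cc, b] && !Rn[cc, a] && !Rn[b, cc], logical(1)))
    if (!via) direct[[length(direct) + 1L]] <- c(a, b)
  }
  direct_edges <- if (length(direct)) {
    d <- data.frame(sub = vapply(direct, `[`, character(1), 1),
                    sup = vapply(direct, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
    d[order(d$sub, d$sup), , drop = FALSE]
  } else data.frame(sub = character(0), sup = character(0),
                    stringsAsFactors = FALSE)
  rownames(direct_edges) <- NULL
  list(subsumptions = subsumptions,
       direct_edges = direct_edges,
       unsatisfiable = sort(unname(vapply(unsat, iri_of, character(1)))))
}
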