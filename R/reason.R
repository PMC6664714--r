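# Saturation-based classification for the supported fragment (EL plus
# class disjointness).
#
# Axioms are first brought to normal form by giving every complex
# subexpression a definitional auxiliary name (both inclusion directions,
# a conservative extension), leaving only:
#   A [= B;  A1 n A2 [= B;  A [= Er.B;  Er.B [= A     (atoms A, B)
# with disjoint(C, D) compiled to C n D [= Bottom.  Completion rules are
# then run to fixpoint over a boolean subsumption matrix S (S[a, b] <=> a
# is subsumed by b), using matrix products for the bulk rules:
#   CR1  a' in S(a), a' [= b            => b in S(a)
#   CR2  c1, c2 in S(a), c1 n c2 [= b   => b in S(a)
#   CR3  a' in S(a), a' [= Er.b         => r-edge (a, b)
#   CR4  edge (a,r,b), b' in S(b), Er.b' [= c => c in S(a)
#   CR5  edge (a,r,b), Bottom in S(b)   => Bottom in S(a)
# This is sound and complete for subsumption between named classes in the
# fragment; unsatisfiable classes are exactly those subsumed by Bottom.
# Auxiliary names are deterministic (the canonical expression rendering in
# a reserved urn: namespace), so repeated runs are identical.

AUX_NS <- "urn:owlet:aux?"

new_normalizer <- function() {
  env <- new.env(parent = emptyenv())
  env$atoms <- character(0)          # all atom IRIs (named + aux + Bottom)
  env$defined <- new.env(parent = emptyenv())  # ce_key -> atom
  env$sub_a <- character(0); env$sub_b <- character(0)        # a [= b
  env$conj_1 <- character(0); env$conj_2 <- character(0); env$conj_b <- character(0)
  env$exr_a <- character(0); env$exr_r <- character(0); env$exr_b <- character(0)
  env$exl_r <- character(0); env$exl_b <- character(0); env$exl_a <- character(0)
  env
}

nz_atom <- function(nz, iri) {
  if (!(iri %in% nz$atoms)) nz$atoms <- c(nz$atoms, iri)
  iri
}

nz_sub <- function(nz, a, b) {
  nz$sub_a <- c(nz$sub_a, a); nz$sub_b <- c(nz$sub_b, b)
}

# Binarized n-ary conjunction of atoms, returning the atom standing for it.
nz_conj_chain <- function(nz, atoms, target) {
  if (length(atoms) == 1) { nz_sub(nz, atoms[1], target); return(invisible()) }
  cur <- atoms[1]
  for (i in 2:length(atoms)) {
    nxt <- if (i == length(atoms)) target else {
      aux <- nz_atom(nz, paste0(AUX_NS, "conj(", cur, ",", atoms[i], ")"))
      aux
    }
    nz$conj_1 <- c(nz$conj_1, cur); nz$conj_2 <- c(nz$conj_2, atoms[i])
    nz$conj_b <- c(nz$conj_b, nxt)
    cur <- nxt
  }
  invisible()
}

# Definitional naming: returns the atom equivalent to expression `ce`.
nz_define <- function(nz, ce) {
  if (ce$kind == "named") return(nz_atom(nz, ce$iri))
  key <- ce_key(ce)
  hit <- nz$defined[[key]]
  if (!is.null(hit)) return(hit)
  atom <- nz_atom(nz, paste0(AUX_NS, key))
  nz$defined[[key]] <- atom
  if (ce$kind == "some") {
    filler <- nz_define(nz, ce$filler)
    nz$exr_a <- c(nz$exr_a, atom); nz$exr_r <- c(nz$exr_r, ce$property)
    nz$exr_b <- c(nz$exr_b, filler)
    nz$exl_r <- c(nz$exl_r, ce$property); nz$exl_b <- c(nz$exl_b, filler)
    nz$exl_a <- c(nz$exl_a, atom)
  } else { # and
    ops <- vapply(ce$operands, function(op) nz_define(nz, op), character(1))
    for (op in ops) nz_sub(nz, atom, op)
    nz_conj_chain(nz, ops, atom)
  }
  atom
}

nz_add_axiom <- function(nz, ax) {
  switch(ax$type,
    subclass = nz_sub(nz, nz_define(nz, ax$sub), nz_define(nz, ax$sup)),
    equivalent = {
      atoms <- vapply(ax$members, function(m) nz_define(nz, m), character(1))
      for (i in seq_len(length(atoms) - 1L)) {
        nz_sub(nz, atoms[i], atoms[i + 1L])
        nz_sub(nz, atoms[i + 1L], atoms[i])
      }
    },
    disjoint = {
      ms <- vapply(ax$members, function(m) nz_atom(nz, m), character(1))
      bot <- nz_atom(nz, OWL_NOTHING)
      cmb <- utils::combn(ms, 2)
      for (j in seq_len(ncol(cmb))) {
        nz$conj_1 <- c(nz$conj_1, cmb[1, j]); nz$conj_2 <- c(nz$conj_2, cmb[2, j])
        nz$conj_b <- c(nz$conj_b, bot)
      }
    },
    # property hierarchies do not participate in classification (documented
    # fragment restriction); declarations/annotations carry no logic
    NULL)
  invisible()
}

# Run completion rules to fixpoint; returns list(S = logical matrix with
# dimnames, atoms, bot).
saturate_normalized <- function(nz) {
  bot <- nz_atom(nz, OWL_NOTHING)
  atoms <- nz$atoms
  n <- length(atoms)
  idx <- stats::setNames(seq_len(n), atoms)
  S <- diag(n) > 0
  M1 <- matrix(0, n, n)
  if (length(nz$sub_a)) M1[cbind(idx[nz$sub_a], idx[nz$sub_b])] <- 1
  conj <- if (length(nz$conj_1)) {
    cbind(idx[nz$conj_1], idx[nz$conj_2], idx[nz$conj_b])
  } else matrix(0L, 0, 3)
  props <- unique(c(nz$exr_r, nz$exl_r))
  E <- lapply(props, function(r) {
    m <- matrix(0, n, n)
    sel <- nz$exr_r == r
    if (any(sel)) m[cbind(idx[nz$exr_a[sel]], idx[nz$exr_b[sel]])] <- 1
    m
  })
  F_ <- lapply(props, function(r) {
    m <- matrix(0, n, n)
    sel <- nz$exl_r == r
    if (any(sel)) m[cbind(idx[nz$exl_b[sel]], idx[nz$exl_a[sel]])] <- 1
    m
  })
  ibot <- idx[[bot]]
  repeat {
    changed <- FALSE
    Snum <- S * 1
    S2 <- S | (Snum %*% M1 > 0)
    for (j in seq_len(nrow(conj))) {
      rows <- S2[, conj[j, 1]] & S2[, conj[j, 2]]
      hit <- rows & !S2[, conj[j, 3]]
      if (any(hit)) S2[hit, conj[j, 3]] <- TRUE
    }
    if (length(props)) {
      S2num <- S2 * 1
      for (k in seq_along(props)) {
        Rel <- (S2num %*% E[[k]]) > 0
        S2 <- S2 | ((Rel * 1) %*% S2num %*% F_[[k]] > 0)
        unsat_targets <- S2[, ibot]
        reach_unsat <- Rel[, unsat_targets, drop = FALSE]
        if (ncol(reach_unsat)) {
          hit <- rowSums(reach_unsat) > 0 & !S2[, ibot]
          if (any(hit)) S2[hit, ibot] <- TRUE
        }
        S2num <- S2 * 1
      }
    }
    changed <- any(S2 != S)
    S <- S2
    if (!changed) break
  }
  dimnames(S) <- list(atoms, atoms)
  list(S = S, atoms = atoms, bot = bot)
}

saturate_axioms <- function(axioms, extra_define = list()) {
  nz <- new_normalizer()
  nz_atom(nz, OWL_NOTHING)
  for (ax in axioms) nz_add_axiom(nz, ax)
  defined <- vapply(extra_define, function(ce) nz_define(nz, ce), character(1))
  sat <- saturate_normalized(nz)
  sat$query_atoms <- defined
  sat
}

sat_subsumed <- function(sat, a, b) {
  unname(sat$S[a, b] | sat$S[a, sat$bot])
}

# ---- Taxonomy --------------------------------------------------------------

#' Classify an ontology document
#'
#' Computes the complete subsumption hierarchy among the named classes of
#' the document by saturation, returning equivalence groups with a
#' canonical representative, the transitively reduced direct edges, and
#' the set of unsatisfiable classes (those subsumed by `owl:Nothing`).
#' Unsatisfiability is reported in the result, never raised.
#'
#' @param doc an ontology document.
#' @return An object of class `owlet_taxonomy` with fields `nodes` (list
#'   of groups: `representative` + `members`), `direct_edges` (data.frame
#'   `sub`, `sup` of node representatives), `unsatisfiable` (character),
#'   `consistent` (logical), and `subsumptions` (data.frame of all
#'   entailed non-reflexive named-class subsumption pairs).
#' @export
classify <- function(doc) {
  named <- signature_of(doc)$classes
  named <- setdiff(named, c(OWL_THING, OWL_NOTHING))
  sat <- saturate_axioms(Filter(is_logical_axiom, doc$axioms))
  present <- intersect(named, sat$atoms)
  isolated <- setdiff(named, present)

  unsat <- present[sat$S[present, sat$bot]]
  satisfiable <- c(setdiff(present, unsat), isolated)

  # subsumption among named classes (unsatisfiable classes subsume into
  # everything)
  subs_pairs <- expand_subsumptions(sat, present, isolated, named, unsat)

  # equivalence groups among satisfiable classes
  groups <- list()
  assigned <- character(0)
  sat_present <- setdiff(present, unsat)
  Ssub <- if (length(sat_present)) {
    sat$S[sat_present, sat_present, drop = FALSE]
  } else matrix(FALSE, 0, 0)
  for (a in sort(satisfiable)) {
    if (a %in% assigned) next
    members <- if (a %in% sat_present) {
      sat_present[Ssub[a, ] & Ssub[, a]]
    } else a
    members <- sort(members)
    assigned <- c(assigned, members)
    groups[[length(groups) + 1L]] <-
      list(representative = members[1], members = members)
  }
  reps <- vapply(groups, `[[`, character(1), "representative")

  # node-level subsumption and transitive reduction
  nrep <- length(reps)
  leq <- matrix(FALSE, nrep, nrep, dimnames = list(reps, reps))
  for (i in seq_len(nrep)) for (j in seq_len(nrep)) {
    if (i == j) next
    a <- reps[i]; b <- reps[j]
    leq[i, j] <- (a %in% sat_present) && (b %in% sat_present) &&
      sat$S[a, b]
  }
  direct <- which(leq, arr.ind = TRUE)
  keep <- logical(nrow(direct))
  for (k in seq_len(nrow(direct))) {
    i <- direct[k, 1]; j <- direct[k, 2]
    via <- any(leq[i, ] & leq[, j])
    keep[k] <- !via
  }
  direct <- direct[keep, , drop = FALSE]
  edges <- data.frame(sub = reps[direct[, 1]], sup = reps[direct[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$sub, edges$sup), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(
    nodes = groups,
    direct_edges = edges,
    unsatisfiable = sort(unsat),
    consistent = TRUE,
    subsumptions = subs_pairs
  ), class = "owlet_taxonomy")
}

expand_subsumptions <- function(sat, present, isolated, named, unsat) {
  subs <- list()
  if (length(present)) {
    Sn <- sat$S[present, present, drop = FALSE]
    hits <- which(Sn, arr.ind = TRUE)
    if (nrow(hits)) {
      subs[[1]] <- data.frame(sub = present[hits[, 1]],
                              sup = present[hits[, 2]],
                              stringsAsFactors = FALSE)
    }
  }
  if (length(unsat)) {
    subs[[length(subs) + 1L]] <- expand.grid(sub = unsat, sup = named,
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  }
  out <- if (length(subs)) do.call(rbind, subs) else {
    data.frame(sub = character(0), sup = character(0), stringsAsFactors = FALSE)
  }
  out <- out[out$sub != out$sup, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$sub, out$sup), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.owlet_taxonomy <- function(x, ...) {
  cat("<owlet_taxonomy>", length(x$nodes), "node(s),",
      nrow(x$direct_edges), "direct edge(s),",
      length(x$unsatisfiable), "unsatisfiable class(es)\n")
  invisible(x)
}

# ---- reason ----------------------------------------------------------------

#' Validate and classify, asserting inferred direct superclasses
#'
#' The two-phase contract of a release reasoner: first logical validation
#' (the ontology must be coherent: consistent with no unsatisfiable
#' classes — if not, an incoherent-ontology error listing the
#' unsatisfiable classes halts execution); then automatic classification,
#' with every direct inferred named-class subsumption not already asserted
#' added to the document.  Edges to `owl:Thing` are never asserted.
#'
#' @param doc an ontology document.
#' @param assert_direct_superclasses add the inferred direct edges
#'   (default `TRUE`).
#' @param fail_on_equivalent_pairs error if two distinct named classes are
#'   inferred equivalent (default `FALSE`).
#' @return The document with inferred direct subsumptions asserted.
#' @export
reason <- function(doc, assert_direct_superclasses = TRUE,
                   fail_on_equivalent_pairs = FALSE) {
  tax <- classify(doc)
  if (length(tax$unsatisfiable)) {
    owlet_stop("owlet_incoherent",
      sprintf("ontology is incoherent: %d unsatisfiable class(es): %s",
              length(tax$unsatisfiable),
              paste(tax$unsatisfiable, collapse = ", ")),
      list(unsatisfiable = tax$unsatisfiable))
  }
  if (fail_on_equivalent_pairs) {
    multi <- Filter(function(g) length(g$members) > 1, tax$nodes)
    if (length(multi)) {
      pairs <- vapply(multi, function(g)
        paste(g$members, collapse = " == "), character(1))
      owlet_stop("owlet_equivalent_pair",
        sprintf("inferred equivalent class pair(s): %s",
                paste(pairs, collapse = "; ")),
        list(groups = multi))
    }
  }
  if (!assert_direct_superclasses) return(doc)
  members_of <- stats::setNames(lapply(tax$nodes, `[[`, "members"),
    vapply(tax$nodes, `[[`, character(1), "representative"))
  new_axioms <- list()
  for (k in seq_len(nrow(tax$direct_edges))) {
    for (a in members_of[[tax$direct_edges$sub[k]]]) {
      for (b in members_of[[tax$direct_edges$sup[k]]]) {
        if (b == OWL_THING) next
        cand <- ax_subclass(ce_named(a), ce_named(b))
        new_axioms[[length(new_axioms) + 1L]] <- cand
      }
    }
  }
  # an edge already asserted (possibly with annotations) is not re-added
  asserted <- vapply(doc$axioms, logical_key, character(1))
  new_axioms <- Filter(function(ax) !(logical_key(ax) %in% asserted),
                       new_axioms)
  doc_add_axioms(doc, new_axioms)
}

# ---- entailment oracle interface ------------------------------------------

#' Is a subsumption axiom entailed?
#'
#' Decides `doc |= sub [= sup` for class expressions in the supported
#' fragment by classifying the document extended with definitional names
#' for both sides.
#'
#' @param doc an ontology document.
#' @param axiom a subclass axiom (other variants are errors).
#' @return Logical scalar.
#' @export
is_entailed <- function(doc, axiom) {
  if (!inherits(axiom, "owlet_axiom") || axiom$type != "subclass") {
    owlet_stop("owlet_usage_error",
               "is_entailed supports subclass axioms only")
  }
  sat <- saturate_axioms(Filter(is_logical_axiom, doc$axioms),
                         extra_define = list(axiom$sub, axiom$sup))
  sat_subsumed(sat, sat$query_atoms[1], sat$query_atoms[2])
}

# Batched existential entailment for materialize: for the given properties,
# return entailed fillers per (named class, property).
entailed_existential_fillers <- function(doc, properties) {
  named <- setdiff(signature_of(doc)$classes, c(OWL_THING, OWL_NOTHING))
  queries <- list()
  for (r in properties) {
    for (b in named) queries[[paste(r, b)]] <- ce_some(r, ce_named(b))
  }
  if (!length(queries)) {
    return(list(named = named, fillers = list(), sat = NULL))
  }
  sat <- saturate_axioms(Filter(is_logical_axiom, doc$axioms),
                         extra_define = queries)
  qatoms <- sat$query_atoms
  fillers <- list()
  present <- intersect(named, sat$atoms)
  i <- 0L
  for (r in properties) {
    for (b in named) {
      i <- i + 1L
      q <- qatoms[i]
      subs <- present[sat$S[present, q] & !sat$S[present, sat$bot]]
      for (a in subs) {
        key <- paste0(a, "\r", r)
        fillers[[key]] <- c(fillers[[key]], b)
      }
    }
  }
  list(named = named, fillers = fillers, sat = sat)
}
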