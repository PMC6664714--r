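# Shared helpers: short IRI constructors and small document builders used
# across the suite.

ex <- function(x) paste0("http://example.org/", x)

iri_label <- "http://www.w3.org/2000/01/rdf-schema#label"
iri_definition <- "http://purl.obolibrary.org/obo/IAO_0000115"

logical_keys <- function(doc) {
  sort(unname(vapply(doc$axioms, logical_key, character(1))))
}

axiom_keys <- function(doc) sort(names(doc$axioms))

subclass_key <- function(a, b) sprintf("sub(<%s>,<%s>)", ex(a), ex(b))

# a small taxonomy document: edges as "A>B" strings meaning A subClassOf B
doc_from_edges <- function(..., extra = list()) {
  edges <- c(...)
  axs <- lapply(strsplit(edges, ">", fixed = TRUE), function(p) {
    ax_subclass(ex(p[1]), ex(p[2]))
  })
  ontology_document(axioms = c(axs, extra))
}

subsumption_set <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$sub, df$sup, sep = " < "))
}

# oracle-side entailment for (possibly complex) subsumption queries:
# name both sides with fresh classes and read the naive closure
oracle_entailed <- function(doc, sub_ce, sup_ce) {
  qx <- "http://example.org/__query_sub"
  qy <- "http://example.org/__query_sup"
  d2 <- doc_add_axioms(doc, list(
    ax_equivalent(list(ce_named(qx), as_ce(sub_ce))),
    ax_equivalent(list(ce_named(qy), as_ce(sup_ce)))))
  subs <- naive_entailed_subsumptions(d2)$subsumptions
  any(subs$sub == qx & subs$sup == qy)
}

# random small fixture for property-style loops
random_fixture <- function(seed, n = NULL) {
  if (is.null(n)) n <- 4 + (seed %% 9)
  generate_fixture(fixture_spec(n_classes = n, n_properties = 2,
                                p_existential = 0.4, seed = seed))
}
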