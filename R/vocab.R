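# Well-known vocabulary IRIs used throughout the package.

NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_OWL  <- "http://www.w3.org/2002/07/owl#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"
NS_OIO  <- "http://www.geneontology.org/formats/oboInOwl#"
NS_OBO  <- "http://purl.obolibrary.org/obo/"
NS_DC   <- "http://purl.org/dc/elements/1.1/"
NS_DCT  <- "http://purl.org/dc/terms/"

RDF_TYPE       <- paste0(NS_RDF, "type")
RDF_FIRST      <- paste0(NS_RDF, "first")
RDF_REST       <- paste0(NS_RDF, "rest")
RDF_NIL        <- paste0(NS_RDF, "nil")

RDFS_LABEL        <- paste0(NS_RDFS, "label")
RDFS_SUBCLASSOF   <- paste0(NS_RDFS, "subClassOf")
RDFS_SUBPROPERTYOF <- paste0(NS_RDFS, "subPropertyOf")
RDFS_ISDEFINEDBY  <- paste0(NS_RDFS, "isDefinedBy")

OWL_CLASS          <- paste0(NS_OWL, "Class")
OWL_OBJECTPROPERTY <- paste0(NS_OWL, "ObjectProperty")
OWL_ANNOTATIONPROPERTY <- paste0(NS_OWL, "AnnotationProperty")
OWL_NAMEDINDIVIDUAL <- paste0(NS_OWL, "NamedIndividual")
OWL_ONTOLOGY       <- paste0(NS_OWL, "Ontology")
OWL_IMPORTS        <- paste0(NS_OWL, "imports")
OWL_VERSIONIRI     <- paste0(NS_OWL, "versionIRI")
OWL_EQUIVALENTCLASS <- paste0(NS_OWL, "equivalentClass")
OWL_DISJOINTWITH   <- paste0(NS_OWL, "disjointWith")
OWL_ALLDISJOINTCLASSES <- paste0(NS_OWL, "AllDisjointClasses")
OWL_MEMBERS        <- paste0(NS_OWL, "members")
OWL_RESTRICTION    <- paste0(NS_OWL, "Restriction")
OWL_ONPROPERTY     <- paste0(NS_OWL, "onProperty")
OWL_SOMEVALUESFROM <- paste0(NS_OWL, "someValuesFrom")
OWL_INTERSECTIONOF <- paste0(NS_OWL, "intersectionOf")
OWL_AXIOM          <- paste0(NS_OWL, "Axiom")
OWL_ANNOTATEDSOURCE   <- paste0(NS_OWL, "annotatedSource")
OWL_ANNOTATEDPROPERTY <- paste0(NS_OWL, "annotatedProperty")
OWL_ANNOTATEDTARGET   <- paste0(NS_OWL, "annotatedTarget")
OWL_DEPRECATED     <- paste0(NS_OWL, "deprecated")
OWL_THING          <- paste0(NS_OWL, "Thing")
OWL_NOTHING        <- paste0(NS_OWL, "Nothing")

XSD_BOOLEAN <- paste0(NS_XSD, "boolean")
XSD_STRING  <- paste0(NS_XSD, "string")

#' Default annotation-property configuration
#'
#' The OBO community conventions pin concepts such as "definition" or
#' "term replaced by" to specific annotation-property IRIs.  Every operation
#' that needs one of these (OBO serialization, QC report, repair, MIREOT)
#' takes a `props` argument defaulting to this list, so deployments using
#' different properties can override any entry.
#'
#' @return Named list of IRIs: `label`, `definition`, `xref`, `subset`,
#'   `deprecated`, `replaced_by`, `source`, `license`, `title`.
#' @export
obo_properties <- function() {
  list(
    label       = RDFS_LABEL,
    definition  = paste0(NS_OBO, "IAO_0000115"),
    xref        = paste0(NS_OIO, "hasDbXref"),
    subset      = paste0(NS_OIO, "inSubset"),
    deprecated  = OWL_DEPRECATED,
    replaced_by = paste0(NS_OBO, "IAO_0100001"),
    source      = RDFS_ISDEFINEDBY,
    license     = paste0(NS_DCT, "license"),
    title       = paste0(NS_DC, "title")
  )
}

default_prefixes <- function() {
  c(
    rdf  = NS_RDF,
    rdfs = NS_RDFS,
    owl  = NS_OWL,
    xsd  = NS_XSD,
    obo  = NS_OBO,
    oboInOwl = NS_OIO,
    dc   = NS_DC,
    dcterms = NS_DCT
  )
}

owlet_error <- function(class, message, data = list()) {
  structure(
    class = c(class, "owlet_error", "error", "condition"),
    c(list(message = message, call = NULL), data)
  )
}

owlet_stop <- function(class, message, data = list()) {
  stop(owlet_error(class, message, data))
}
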