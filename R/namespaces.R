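#' Well-known RDF namespaces used throughout the package
#'
#' Prefix bindings for the FHIR R4 RDF vocabulary, R2RML, RDF, XSD, the
#' GraphDB-style SPARQL function namespace, and the default base IRI under
#' which resource instances are minted (`<base>/<ResourceType>/<id>`).
#'
#' @return Named character vector mapping prefix to namespace IRI.
#' @export
ckg_namespaces <- function() {
  c(
    fhir = "http://hl7.org/fhir/",
    rr   = "http://www.w3.org/ns/r2rml#",
    rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    xsd  = "http://www.w3.org/2001/XMLSchema#",
    ofn  = "http://www.ontotext.com/sparql/functions/",
    ckg  = ckg_base_iri()
  )
}

#' Default base IRI for materialized instances
#' @return Character scalar.
#' @export
ckg_base_iri <- function() "http://example.org/fhir/"

NS_FHIR <- "http://hl7.org/fhir/"
NS_RR   <- "http://www.w3.org/ns/r2rml#"
NS_RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_XSD  <- "http://www.w3.org/2001/XMLSchema#"
NS_OFN  <- "http://www.ontotext.com/sparql/functions/"

RDF_TYPE <- paste0(NS_RDF, "type")

fhir_iri <- function(local) paste0(NS_FHIR, local)
xsd_iri  <- function(local) paste0(NS_XSD, local)
rr_iri   <- function(local) paste0(NS_RR, local)

#' Expand a prefixed name against a prefix map
#'
#' @param x Character vector of prefixed names (`pfx:local`) or absolute IRIs.
#' @param prefixes Named character vector, prefix -> namespace IRI.
#' @return Character vector of absolute IRIs.
#' @keywords internal
expand_curie <- function(x, prefixes) {
  vapply(x, function(term) {
    if (grepl("^(https?|urn|file|mailto):", term)) return(term)
    m <- regmatches(term, regexec("^([A-Za-z][A-Za-z0-9_.-]*)?:(.*)$", term))[[1]]
    if (length(m) == 0) return(term)
    pfx <- m[2]
    if (!pfx %in% names(prefixes)) {
      stop("undeclared prefix '", pfx, "' in '", term, "'", call. = FALSE)
    }
    paste0(prefixes[[pfx]], m[3])
  }, character(1), USE.NAMES = FALSE)
}

# Compact an absolute IRI to pfx:local when a declared namespace prefixes it.
compact_iri <- function(x, prefixes) {
  vapply(x, function(iri) {
    for (pfx in names(prefixes)) {
      ns <- prefixes[[pfx]]
      if (startsWith(iri, ns)) {
        local <- substring(iri, nchar(ns) + 1L)
        # only safe when the remainder is a plain PN_LOCAL token
        if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) && !endsWith(local, ".")) {
          return(paste0(pfx, ":", local))
        }
      }
    }
    paste0("<", iri, ">")
  }, character(1), USE.NAMES = FALSE)
}

# Local name of an IRI: text after the last '.', '#' or '/'.
# fhir element predicates ("fhir:Patient.birthDate") yield the element name.
iri_local_name <- function(iri) {
  local <- sub("^.*[#/]", "", iri)
  sub("^.*\\.", "", local)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
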