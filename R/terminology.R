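# OMOP vocabulary_id -> preferred FHIR Coding System URI translation, and the
# CodeableConcept constructor used for standalone concept nodes.

#' Translation table: OMOP vocabulary_id to preferred Coding System URI
#'
#' The 13 externally published FHIR code systems that have counterparts among
#' the OMOP vocabulary ids (SNOMED, RxNorm, LOINC, UCUM, CPT4, NDFRT, NDC,
#' CVX, ICD9CM/ICD10/ICD10CM, ATC, NUCC, HGNC, ClinVar; the ICD family shares
#' one slot). The FHIR terminology registry publishes these under `http://`
#' IRIs; `https_snomed = TRUE` switches SNOMED to the `https://` form some
#' deployments use.
#'
#' @param https_snomed Use `https://snomed.info/sct` instead of the registry
#'   `http://` form. Default `FALSE`.
#' @return Data frame with columns `vocabulary_id`, `system_uri`.
#' @export
coding_system_table <- function(https_snomed = FALSE) {
  tab <- data.frame(
    vocabulary_id = c("SNOMED", "RxNorm", "LOINC", "UCUM", "CPT4", "NDFRT",
                      "NDC", "CVX", "ICD9CM", "ICD10", "ICD10CM", "ATC",
                      "NUCC", "HGNC", "ClinVar"),
    system_uri = c(
      "http://snomed.info/sct",
      "http://www.nlm.nih.gov/research/umls/rxnorm",
      "http://loinc.org",
      "http://unitsofmeasure.org",
      "http://www.ama-assn.org/go/cpt",
      "http://hl7.org/fhir/ndfrt",
      "http://hl7.org/fhir/sid/ndc",
      "http://hl7.org/fhir/sid/cvx",
      "http://hl7.org/fhir/sid/icd-9-cm",
      "http://hl7.org/fhir/sid/icd-10",
      "http://hl7.org/fhir/sid/icd-10-cm",
      "http://www.whocc.no/atc",
      "http://nucc.org/provider-taxonomy",
      "http://www.genenames.org",
      "http://www.ncbi.nlm.nih.gov/clinvar"),
    stringsAsFactors = FALSE
  )
  if (https_snomed) {
    tab$system_uri[tab$vocabulary_id == "SNOMED"] <- "https://snomed.info/sct"
  }
  tab
}

#' Translate an OMOP vocabulary_id to its preferred Coding System URI
#'
#' Vocabularies without a published FHIR counterpart keep the OMOP
#' convention: the raw vocabulary_id is returned unchanged.
#'
#' @param vocabulary_id Character vector of OMOP vocabulary ids.
#' @param table Translation table; defaults to [coding_system_table()].
#' @return Character vector of system URIs (or raw ids).
#' @export
translate_system <- function(vocabulary_id, table = coding_system_table()) {
  idx <- match(vocabulary_id, table$vocabulary_id)
  out <- table$system_uri[idx]
  out[is.na(idx)] <- vocabulary_id[is.na(idx)]
  out
}

#' Gender concept translation map
#'
#' Administrative-gender code literals derived from OMOP gender_concept_id.
#' 8507 -> "male" and 8532 -> "female" by OMOP convention; anything else maps
#' to "unknown". Overridable.
#'
#' @return Named character vector, concept_id (as name) -> code.
#' @export
default_gender_map <- function() c("8507" = "male", "8532" = "female")

#' Build the FHIR RDF triples of a CodeableConcept node
#'
#' Emits a CodeableConcept with one coding child carrying `system` (via
#' [translate_system()]), `code` (= concept_code), `display` (= concept_name),
#' plus a `text` arc (= concept_name). A NULL/NA concept_code omits the
#' coding child and keeps the text arc.
#'
#' @param concept_row Named list or one-row data frame with `concept_id`,
#'   `concept_code`, `concept_name`, `vocabulary_id`.
#' @param node IRI of the CodeableConcept node; defaults to
#'   `<base>/CodeableConcept/<concept_id>`.
#' @param system_table Translation table for [translate_system()].
#' @return Data frame of triples (same columns as an `rdf_graph`'s).
#' @export
build_codeable_concept <- function(concept_row,
                                   node = NULL,
                                   system_table = coding_system_table()) {
  row <- as.list(concept_row)
  node <- node %||% paste0(ckg_base_iri(), "CodeableConcept/", row$concept_id)
  lit <- function(s, p, o, dt = xsd_iri("string")) {
    data.frame(subject = s, predicate = p, object = as.character(o),
               object_type = "literal", datatype = dt,
               stringsAsFactors = FALSE)
  }
  iri <- function(s, p, o) {
    data.frame(subject = s, predicate = p, object = o, object_type = "iri",
               datatype = NA_character_, stringsAsFactors = FALSE)
  }
  value_node <- function(parent, pred, label, value) {
    child <- paste0(parent, "/", label)
    rbind(iri(parent, pred, child),
          lit(child, fhir_iri("value"), value))
  }
  out <- iri(node, RDF_TYPE, fhir_iri("CodeableConcept"))
  has_text <- !is.null(row$concept_name) && !is.na(row$concept_name)
  if (has_text) {
    out <- rbind(out, value_node(node, fhir_iri("CodeableConcept.text"),
                                 "text", row$concept_name))
  }
  has_code <- !is.null(row$concept_code) && !is.na(row$concept_code)
  if (has_code) {
    coding <- paste0(node, "/coding")
    out <- rbind(
      out,
      iri(node, fhir_iri("CodeableConcept.coding"), coding),
      value_node(coding, fhir_iri("Coding.system"), "system",
                 translate_system(row$vocabulary_id, system_table)),
      value_node(coding, fhir_iri("Coding.code"), "code", row$concept_code))
    if (has_text) {
      out <- rbind(out, value_node(coding, fhir_iri("Coding.display"),
                                   "display", row$concept_name))
    }
  }
  out
}
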