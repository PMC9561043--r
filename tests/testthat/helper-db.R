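# Shared fixtures: every database is built in code at test time.

make_db <- function() {
  con <- omop_connect()
  create_schema(con)
  seed_vocabulary(con)
  con
}

make_synthetic_db <- function(n_persons = 40L,
                              planted = c(Q1 = 3L, Q2 = 2L, Q3 = 1L,
                                          Q4 = 2L, Q5 = 2L),
                              seed = 42L, ...) {
  con <- make_db()
  gt <- generate_synthetic(
    synthetic_config(n_persons = n_persons, planted = planted, seed = seed,
                     ...), con)
  list(con = con, gt = gt)
}

# A minimal person -> Patient entry in the style of the shipped mapping.
TML_PREFIXES <- paste(
  "@prefix fhir: <http://hl7.org/fhir/> .",
  "@prefix rr: <http://www.w3.org/ns/r2rml#> .",
  "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
  "@prefix map: <http://example.org/mappings/test#> .",
  sep = "\n")

tml_patient_entry <- function(body = NULL) {
  body <- body %||% paste(
    "    fhir:nodeRole [ rr:constant fhir:treeRoot ] ;",
    "    fhir:Resource.id [ fhir:value [ rr:column \"person_id\" ] ] ;",
    "    fhir:Patient.birthDate [ fhir:value [",
    "      rr:column \"birth_date\" ; rr:datatype xsd:date ] ]",
    sep = "\n")
  paste0(TML_PREFIXES, "\n\nmap:Patient\n",
    "  rr:logicalTable [ rr:sqlQuery \"\"\"SELECT person_id,\n",
    "      date(birth_datetime) AS birth_date FROM person\"\"\" ] ;\n",
    "  rr:subjectMap [ rr:template ",
    "\"http://example.org/fhir/Patient/{person_id}\" ;\n",
    "                  rr:class fhir:Patient ] ;\n",
    "  rr:predicateObjectMap [\n", body, "\n  ] .\n")
}
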