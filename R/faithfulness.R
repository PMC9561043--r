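# Demonstration query suite: five cohort questions answered both in SQL over
# the OMOP database and in SPARQL over the materialized graph. Faithful
# transformation means the two person-id sets are identical for every query.
#
# The SQL side uses the OMOP "magic values" directly (gender_concept_id =
# 8507, visit_concept_id IN (9201, 262)); the SPARQL side uses the FHIR
# vocabulary the graph carries ('male', the "IP" encounter class workaround)
# and the registered datetime-duration extension function for the
# greater-than-five-days criterion.

#' The five demonstration query pairs
#'
#' Q1: male patients with an inpatient admission lasting strictly more than
#' 5 days. Q2: patients with an Alzheimer's disease diagnosis. Q3: patients
#' who delivered a baby. Q4: patients prescribed trazodone. Q5: patients
#' with an HbA1c result >= 10. Cohort concepts are selected by concept_id
#' from the seeded vocabulary, not by name matching.
#'
#' @param concepts Concept-id configuration; defaults to [query_concepts()].
#' @param vocab Vocabulary frame used to resolve concept codes and coding
#'   systems for the SPARQL side; defaults to [default_vocabulary()].
#' @param encounter_code Encounter class code the graph carries for
#'   inpatient visits (`"IP"` default, or `"IMP"`).
#' @return Named list of `query_spec` objects (`id`, `description`, `sql`,
#'   `sparql`).
#' @export
demo_queries <- function(concepts = query_concepts(),
                         vocab = default_vocabulary(),
                         encounter_code = "IP") {
  code_of <- function(id) vocab$concept_code[vocab$concept_id == id]
  system_of <- function(id) {
    translate_system(vocab$vocabulary_id[vocab$concept_id == id])
  }
  prologue <- paste0(
    "PREFIX fhir: <", NS_FHIR, ">\n",
    "PREFIX xsd: <", NS_XSD, ">\n",
    "PREFIX ofn: <", NS_OFN, ">\n")
  spec <- function(id, description, sql, sparql) {
    structure(list(id = id, description = description, sql = sql,
                   sparql = paste0(prologue, sparql)),
              class = "query_spec")
  }
  in_list <- paste(concepts$inpatient, collapse = ", ")
  list(
    Q1 = spec("Q1",
      "Identify male patients with inpatient admissions lasting greater than 5 days.",
      paste0(
        "SELECT DISTINCT p.person_id\n",
        "FROM person p\n",
        "JOIN visit_occurrence v ON v.person_id = p.person_id\n",
        "WHERE p.gender_concept_id = ", concepts$male, "\n",
        "  AND v.visit_concept_id IN (", in_list, ")\n",
        "  AND julianday(v.visit_end_datetime) - julianday(v.visit_start_datetime) > 5"),
      paste0(
        "SELECT DISTINCT ?pid WHERE {\n",
        "  ?patient a fhir:Patient ;\n",
        "    fhir:Resource.id [ fhir:value ?pid ] ;\n",
        "    fhir:Patient.gender [ fhir:value ?gender ] .\n",
        "  ?enc a fhir:Encounter ;\n",
        "    fhir:Encounter.subject [ fhir:link ?patient ] ;\n",
        "    fhir:Encounter.class [ fhir:Coding.code [ fhir:value ?type ] ] ;\n",
        "    fhir:Encounter.period [\n",
        "      fhir:Period.start [ fhir:value ?start ] ;\n",
        "      fhir:Period.end [ fhir:value ?end ] ] .\n",
        "  FILTER (?gender = 'male')\n",
        "  FILTER (?type = '", encounter_code, "')\n",
        "  FILTER (ofn:daysBetween(?start, ?end) > 5)\n",
        "}")),
    Q2 = spec("Q2",
      "Identify patients diagnosed with Alzheimer's disease.",
      paste0(
        "SELECT DISTINCT person_id FROM condition_occurrence\n",
        "WHERE condition_concept_id = ", concepts$alzheimer),
      paste0(
        "SELECT DISTINCT ?pid WHERE {\n",
        "  ?cond a fhir:Condition ;\n",
        "    fhir:Condition.subject [ fhir:link ?patient ] ;\n",
        "    fhir:Condition.code [ fhir:CodeableConcept.coding [\n",
        "      fhir:Coding.system [ fhir:value ?system ] ;\n",
        "      fhir:Coding.code [ fhir:value ?code ] ] ] .\n",
        "  ?patient fhir:Resource.id [ fhir:value ?pid ] .\n",
        "  FILTER (?system = '", system_of(concepts$alzheimer), "')\n",
        "  FILTER (?code = '", code_of(concepts$alzheimer), "')\n",
        "}")),
    Q3 = spec("Q3",
      "Identify patients who delivered a baby.",
      paste0(
        "SELECT DISTINCT person_id FROM procedure_occurrence\n",
        "WHERE procedure_concept_id = ", concepts$delivery),
      paste0(
        "SELECT DISTINCT ?pid WHERE {\n",
        "  ?proc a fhir:Procedure ;\n",
        "    fhir:Procedure.subject [ fhir:link ?patient ] ;\n",
        "    fhir:Procedure.code [ fhir:CodeableConcept.coding [\n",
        "      fhir:Coding.system [ fhir:value ?system ] ;\n",
        "      fhir:Coding.code [ fhir:value ?code ] ] ] .\n",
        "  ?patient fhir:Resource.id [ fhir:value ?pid ] .\n",
        "  FILTER (?system = '", system_of(concepts$delivery), "')\n",
        "  FILTER (?code = '", code_of(concepts$delivery), "')\n",
        "}")),
    Q4 = spec("Q4",
      "Identify patients prescribed trazodone.",
      paste0(
        "SELECT DISTINCT person_id FROM drug_exposure\n",
        "WHERE drug_concept_id = ", concepts$trazodone),
      paste0(
        "SELECT DISTINCT ?pid WHERE {\n",
        "  ?ms a fhir:MedicationStatement ;\n",
        "    fhir:MedicationStatement.subject [ fhir:link ?patient ] ;\n",
        "    fhir:MedicationStatement.medicationCodeableConcept [\n",
        "      fhir:CodeableConcept.coding [\n",
        "        fhir:Coding.system [ fhir:value ?system ] ;\n",
        "        fhir:Coding.code [ fhir:value ?code ] ] ] .\n",
        "  ?patient fhir:Resource.id [ fhir:value ?pid ] .\n",
        "  FILTER (?system = '", system_of(concepts$trazodone), "')\n",
        "  FILTER (?code = '", code_of(concepts$trazodone), "')\n",
        "}")),
    Q5 = spec("Q5",
      "Identify patients with an HbA1c result >= 10 %.",
      paste0(
        "SELECT DISTINCT person_id FROM measurement\n",
        "WHERE measurement_concept_id = ", concepts$hba1c, "\n",
        "  AND value_as_number >= 10"),
      paste0(
        "SELECT DISTINCT ?pid WHERE {\n",
        "  ?obs a fhir:Observation ;\n",
        "    fhir:Observation.subject [ fhir:link ?patient ] ;\n",
        "    fhir:Observation.code [ fhir:CodeableConcept.coding [\n",
        "      fhir:Coding.code [ fhir:value ?code ] ] ] ;\n",
        "    fhir:Observation.effectiveDateTime [ fhir:value ?dt ] ;\n",
        "    fhir:Observation.valueQuantity [\n",
        "      fhir:Quantity.value [ fhir:value ?val ] ] .\n",
        "  ?patient fhir:Resource.id [ fhir:value ?pid ] .\n",
        "  BIND (ofn:toDate(?dt) AS ?date)\n",
        "  FILTER (?code = '", code_of(concepts$hba1c), "')\n",
        "  FILTER (?val >= 10)\n",
        "}"))
  )
}

#' Run a query's SQL form
#'
#' @param con A `DBIConnection`.
#' @param q A `query_spec`.
#' @return Sorted integer vector of distinct person ids.
#' @export
run_sql <- function(con, q) {
  sort(unique(as.integer(DBI::dbGetQuery(con, q$sql)[[1]])))
}

#' Run a query's SPARQL form over the materialized graph
#'
#' Person ids are recovered from the `fhir:Resource.id` values of the
#' matched Patient instances.
#'
#' @param graph An `rdf_graph`.
#' @param q A `query_spec`.
#' @param functions SPARQL extension registry; defaults to
#'   [sparql_functions()].
#' @return Sorted integer vector of distinct person ids.
#' @export
run_sparql <- function(graph, q, functions = sparql_functions()) {
  res <- sparql_query(graph, q$sparql, functions = functions)
  sort(unique(as.integer(res[[1]])))
}

#' Compare SQL and SPARQL cohorts for a query suite
#'
#' @param con A `DBIConnection` holding the OMOP data.
#' @param graph The `rdf_graph` materialized from the same database with the
#'   same mapping.
#' @param suite List of `query_spec`; defaults to [demo_queries()].
#' @param ground_truth Optional `ckg_ground_truth` from
#'   [generate_synthetic()]; when given, three-way agreement is reported.
#' @return An object of class `faithfulness_report`: `per_query` data frame
#'   (`id`, `sql_count`, `sparql_count`, `identical`, and
#'   `matches_ground_truth` when available), `cohorts` (per-query id sets),
#'   and `all_identical`.
#' @export
compare_cohorts <- function(con, graph, suite = demo_queries(),
                            ground_truth = NULL) {
  rows <- list()
  cohorts <- list()
  for (q in suite) {
    sql_ids <- run_sql(con, q)
    sparql_ids <- run_sparql(graph, q)
    same <- setequal(sql_ids, sparql_ids)
    gt_ok <- if (!is.null(ground_truth)) {
      setequal(sql_ids, ground_truth$cohorts[[q$id]]) && same
    } else NA
    rows[[q$id]] <- data.frame(
      id = q$id, sql_count = length(sql_ids),
      sparql_count = length(sparql_ids), identical = same,
      matches_ground_truth = gt_ok, stringsAsFactors = FALSE)
    cohorts[[q$id]] <- list(sql_ids = sql_ids, sparql_ids = sparql_ids)
  }
  per_query <- do.call(rbind, rows)
  rownames(per_query) <- NULL
  structure(list(per_query = per_query, cohorts = cohorts,
                 all_identical = all(per_query$identical)),
            class = "faithfulness_report")
}

#' @export
print.faithfulness_report <- function(x, ...) {
  cat("<faithfulness_report>\n")
  print(x$per_query, row.names = FALSE)
  cat(if (x$all_identical) "all queries identical: faithful transformation\n"
      else "MISMATCH: transformation not faithful\n")
  invisible(x)
}
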