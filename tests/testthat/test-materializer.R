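test_that("NULL columns suppress arcs: no address or practitioner emitted", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  load_rows(con, "person", data.frame(
    person_id = 1L, gender_concept_id = 8507L,
    birth_datetime = "1950-06-07T08:09:10"))
  g <- materialize_tml(con, fhir_mapping())
  tr <- g$triples
  patient <- "http://example.org/fhir/Patient/1"
  expect_true(any(tr$subject == patient &
                    tr$predicate == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
                    tr$object == "http://hl7.org/fhir/Patient"))
  gender_node <- tr$object[tr$subject == patient &
                             tr$predicate == "http://hl7.org/fhir/Patient.gender"]
  expect_length(gender_node, 1)
  expect_equal(tr$object[tr$subject == gender_node &
                           tr$predicate == "http://hl7.org/fhir/value"],
               "male")
  expect_true(any(tr$predicate == "http://hl7.org/fhir/Patient.birthDate"))
  expect_false(any(tr$predicate == "http://hl7.org/fhir/Patient.address"))
  expect_false(any(tr$predicate ==
                     "http://hl7.org/fhir/Patient.generalPractitioner"))
  # every mapped non-NULL cell contributed: birthDate literal is the date part
  bd_node <- tr$object[tr$subject == patient &
                         tr$predicate == "http://hl7.org/fhir/Patient.birthDate"]
  bd <- tr[tr$subject == bd_node & tr$predicate == "http://hl7.org/fhir/value", ]
  expect_equal(bd$object, "1950-06-07")
  expect_equal(bd$datatype, "http://www.w3.org/2001/XMLSchema#date")
})

test_that("an empty database materializes an empty graph", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "DELETE FROM concept")
  g <- materialize_tml(con, fhir_mapping())
  expect_equal(graph_size(g), 0)
})

test_that("person_filter restricts the graph to the requested persons", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  load_rows(con, "person", data.frame(
    person_id = 1:3, gender_concept_id = 8507L,
    birth_datetime = paste0(1950:1952, "-01-01T00:00:00")))
  maps <- compile_tml(fhir_mapping())
  full <- materialize(con, maps)
  filtered <- materialize(con, maps, person_filter = 2L)
  patients_in <- function(g) {
    unique(g$triples$subject[g$triples$object == "http://hl7.org/fhir/Patient"])
  }
  expect_equal(patients_in(filtered), "http://example.org/fhir/Patient/2")
  # oracle: running unfiltered and subsetting by subject IRI gives the same set
  expect_setequal(patients_in(filtered),
                  grep("/Patient/2$", patients_in(full), value = TRUE))
  expect_equal(unname(graph_stats(filtered)["http://hl7.org/fhir/Patient"]), 1L)
})

test_that("coding system translation covers 13 published systems", {
  tab <- coding_system_table()
  expect_equal(translate_system("SNOMED"), "http://snomed.info/sct")
  expect_equal(translate_system("LOINC"), "http://loinc.org")
  expect_equal(translate_system("MyLocalVocab"), "MyLocalVocab")
  families <- unique(sub("^ICD.*", "ICD[x]", tab$vocabulary_id))
  expect_length(families, 13)
  expect_equal(
    coding_system_table(https_snomed = TRUE)$system_uri[
      tab$vocabulary_id == "SNOMED"], "https://snomed.info/sct")
})

test_that("build_codeable_concept emits coding and text, degrading on NULLs", {
  row <- list(concept_id = 378419L, concept_code = "26929004",
              concept_name = "Alzheimer's disease", vocabulary_id = "SNOMED")
  tr <- build_codeable_concept(row)
  val <- function(frag) {
    node <- tr$object[grepl(frag, tr$predicate)]
    tr$object[tr$subject %in% node & tr$predicate == "http://hl7.org/fhir/value"]
  }
  expect_equal(val("Coding.system$"), "http://snomed.info/sct")
  expect_equal(val("Coding.code$"), "26929004")
  expect_equal(val("Coding.display$"), "Alzheimer's disease")
  expect_equal(val("CodeableConcept.text$"), "Alzheimer's disease")

  row$vocabulary_id <- "MyLocalVocab"
  expect_equal(build_codeable_concept(row)$object[
    grepl("value", build_codeable_concept(row)$predicate) &
      grepl("/system$", build_codeable_concept(row)$subject)][1],
    "MyLocalVocab")

  row$concept_code <- NA
  tr2 <- build_codeable_concept(row)
  expect_false(any(grepl("CodeableConcept.coding$", tr2$predicate)))
  expect_true(any(grepl("CodeableConcept.text$", tr2$predicate)))
})

test_that("mapping-driven CodeableConcept agrees with the constructor", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  g <- materialize_tml(con, fhir_mapping())
  row <- DBI::dbGetQuery(con,
    "SELECT concept_id, concept_code, concept_name, vocabulary_id
     FROM concept WHERE concept_id = 378419")
  expected <- build_codeable_concept(row)
  keys <- function(df) paste(df$subject, df$predicate, df$object)
  expect_true(all(keys(expected) %in% keys(g$triples)))
})

test_that("adding rows never removes triples", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  load_rows(con, "person", data.frame(
    person_id = 1L, gender_concept_id = 8507L,
    birth_datetime = "1950-01-01T00:00:00"))
  maps <- compile_tml(fhir_mapping())
  before <- materialize(con, maps)
  load_rows(con, "person", data.frame(
    person_id = 2L, gender_concept_id = 8532L,
    birth_datetime = "1960-01-01T00:00:00"))
  after <- materialize(con, maps)
  keys <- function(g) paste(g$triples$subject, g$triples$predicate,
                            g$triples$object)
  expect_true(all(keys(before) %in% keys(after)))
  expect_gt(graph_size(after), graph_size(before))
})

test_that("IRI template values are percent-encoded, never a failure", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  load_rows(con, "concept_relationship", data.frame(
    concept_id_1 = 1L, concept_id_2 = 2L, relationship_id = "Maps to"))
  # relationship_id flows into a literal; subject uses ids only
  g <- materialize_tml(con, fhir_mapping())
  expect_true(any(grepl("ConceptMap/rel-1-2$", g$triples$subject)))
  # direct check of the encoder
  df <- data.frame(x = "a b/c", stringsAsFactors = FALSE)
  out <- fhirckg:::expand_template("http://e.org/{x}", df)
  expect_equal(out, "http://e.org/a%20b%2Fc")
})

test_that("graph stats count typed subjects per resource type", {
  expect_equal(unname(graph_stats(rdf_graph(), "http://hl7.org/fhir/Patient")),
               0L)
  db <- make_synthetic_db(n_persons = 12L,
                          planted = c(Q1 = 1L, Q2 = 1L, Q3 = 0L,
                                      Q4 = 1L, Q5 = 1L))
  on.exit(DBI::dbDisconnect(db$con))
  g <- materialize_tml(db$con, fhir_mapping())
  expect_equal(unname(graph_stats(g)[["http://hl7.org/fhir/Patient"]]), 12L)
})
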