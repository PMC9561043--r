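test_that("duration_days computes exact day fractions", {
  expect_equal(duration_days("2001-01-01T00:00:00", "2001-01-06T00:00:00"), 5)
  expect_equal(duration_days("2001-01-01T00:00:00", "2001-01-01T00:00:00"), 0)
  # oracle: epoch-second subtraction / 86400
  s <- as.numeric(as.POSIXct("2001-01-01T00:00:00",
                             format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  e <- as.numeric(as.POSIXct("2001-01-06T12:00:00",
                             format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  expect_equal(duration_days("2001-01-01T00:00:00", "2001-01-06T12:00:00"),
               (e - s) / 86400)
  expect_equal(duration_days("2001-01-06T00:00:00", "2001-01-01T00:00:00"), -5)
  expect_warning(out <- duration_days("not-a-date", "2001-01-01T00:00:00"),
                 "unparseable")
  expect_true(is.na(out))
})

small_graph <- function() {
  lit <- function(s, p, o, dt = "http://www.w3.org/2001/XMLSchema#string") {
    data.frame(subject = s, predicate = p, object = o,
               object_type = "literal", datatype = dt,
               stringsAsFactors = FALSE)
  }
  iri <- function(s, p, o) {
    data.frame(subject = s, predicate = p, object = o, object_type = "iri",
               datatype = NA_character_, stringsAsFactors = FALSE)
  }
  ex <- function(x) paste0("http://example.org/", x)
  rdf_graph(rbind(
    iri(ex("p1"), "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
        "http://hl7.org/fhir/Patient"),
    iri(ex("p1"), "http://hl7.org/fhir/Patient.gender", ex("p1/gender")),
    lit(ex("p1/gender"), "http://hl7.org/fhir/value", "male"),
    iri(ex("p2"), "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
        "http://hl7.org/fhir/Patient"),
    iri(ex("p2"), "http://hl7.org/fhir/Patient.gender", ex("p2/gender")),
    lit(ex("p2/gender"), "http://hl7.org/fhir/value", "female"),
    iri(ex("e1"), "http://hl7.org/fhir/Encounter.subject", ex("p1")),
    lit(ex("e1"), "http://hl7.org/fhir/days", "7.5",
        "http://www.w3.org/2001/XMLSchema#decimal")
  ))
}

test_that("basic graph patterns join across shared variables", {
  g <- small_graph()
  out <- sparql_query(g, "
    PREFIX fhir: <http://hl7.org/fhir/>
    SELECT DISTINCT ?p WHERE {
      ?p a fhir:Patient .
      ?e fhir:Encounter.subject ?p .
    }")
  expect_equal(out$p, "http://example.org/p1")
})

test_that("filters compare strings and numbers with SPARQL semantics", {
  g <- small_graph()
  out <- sparql_query(g, "
    PREFIX fhir: <http://hl7.org/fhir/>
    SELECT DISTINCT ?p WHERE {
      ?p fhir:Patient.gender [ fhir:value ?g ] .
      FILTER (?g = 'female')
    }")
  expect_equal(out$p, "http://example.org/p2")
  out <- sparql_query(g, "
    PREFIX fhir: <http://hl7.org/fhir/>
    SELECT ?e WHERE { ?e fhir:days ?d . FILTER (?d > 5) }")
  expect_equal(out$e, "http://example.org/e1")
  out <- sparql_query(g, "
    PREFIX fhir: <http://hl7.org/fhir/>
    SELECT ?e WHERE { ?e fhir:days ?d . FILTER (?d > 7.5) }")
  expect_equal(nrow(out), 0)
  out <- sparql_query(g, "
    PREFIX fhir: <http://hl7.org/fhir/>
    SELECT DISTINCT ?p WHERE {
      ?p fhir:Patient.gender [ fhir:value ?g ] .
      FILTER (?g = 'male' || ?g = 'female')
    }")
  expect_equal(nrow(out), 2)
})

test_that("BIND and extension functions evaluate per binding", {
  g <- small_graph()
  out <- sparql_query(g, "
    PREFIX fhir: <http://hl7.org/fhir/>
    PREFIX ofn: <http://www.ontotext.com/sparql/functions/>
    SELECT ?p ?dur WHERE {
      ?p a fhir:Patient .
      BIND (ofn:daysBetween('2001-01-01T00:00:00', '2001-01-03T12:00:00')
            AS ?dur)
      FILTER (?dur > 2)
    }")
  expect_equal(nrow(out), 2)
  expect_equal(unique(out$dur), "2.5")
})

test_that("an unregistered function raises an instructive error", {
  g <- small_graph()
  expect_error(sparql_query(g, "
    PREFIX ofn: <http://www.ontotext.com/sparql/functions/>
    PREFIX fhir: <http://hl7.org/fhir/>
    SELECT ?p WHERE { ?p a fhir:Patient .
      FILTER (ofn:noSuchFn(?p) > 1) }"),
    "unbound SPARQL function")
})

test_that("queries over an empty graph return empty bindings", {
  out <- sparql_query(rdf_graph(), "
    PREFIX fhir: <http://hl7.org/fhir/>
    SELECT DISTINCT ?p WHERE { ?p a fhir:Patient . }")
  expect_equal(nrow(out), 0)
})
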