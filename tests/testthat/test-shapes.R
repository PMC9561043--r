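test_that("the shipped schema loads with 11 resource shapes", {
  schema <- load_shapes()
  kinds <- vapply(schema$shapes, function(s) s$kind, character(1))
  expect_equal(sum(kinds == "resource"), 11)
  expect_true(all(c("String", "Code", "Date", "DateTime", "Decimal")
                  %in% names(schema$shapes)[kinds == "primitive"]))
})

test_that("dangling shape references are rejected at load time", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "prefixes: {fhir: 'http://hl7.org/fhir/'}",
    "shapes:",
    "  Patient:",
    "    kind: resource",
    "    type: 'fhir:Patient'",
    "    constraints:",
    "      - {path: 'fhir:Resource.id', min: 1, shape: Foo}"), path)
  expect_error(load_shapes(path), "dangling shape reference 'Foo'")
})

test_that("an empty schema validates vacuously", {
  path <- tempfile(fileext = ".yaml")
  writeLines("shapes: {}", path)
  schema <- load_shapes(path)
  rep <- validate_graph(rdf_graph(), schema)
  expect_equal(nrow(rep$per_type), 0)
  expect_true(is.na(rep$overall_conformance))
})

test_that("a materialized synthetic graph is fully conformant", {
  db <- make_synthetic_db(n_persons = 30L, seed = 4L)
  on.exit(DBI::dbDisconnect(db$con))
  g <- materialize_tml(db$con, fhir_mapping())
  rep <- validate_graph(g, load_shapes())
  expect_equal(rep$overall_conformance, 1)
  expect_equal(nrow(rep$violations), 0)
  expect_true(all(rep$per_type$conformant == rep$per_type$checked))
})

test_that("deleting one gender value arc flags exactly that Patient", {
  db <- make_synthetic_db(n_persons = 20L, seed = 6L)
  on.exit(DBI::dbDisconnect(db$con))
  g <- materialize_tml(db$con, fhir_mapping())
  victim <- "http://example.org/fhir/Patient/3/gender"
  tr <- g$triples
  drop <- tr$subject == victim & tr$predicate == "http://hl7.org/fhir/value"
  expect_equal(sum(drop), 1)
  g$triples <- tr[!drop, , drop = FALSE]
  rep <- validate_graph(g, load_shapes())
  expect_equal(rep$violations$root, "http://example.org/fhir/Patient/3")
  per <- rep$per_type
  patient_row <- per$type == "http://hl7.org/fhir/Patient"
  expect_equal(per$conformant[patient_row], per$checked[patient_row] - 1L)
  expect_true(all(per$conformant[!patient_row] == per$checked[!patient_row]))
})

test_that("a dateTime leaf typed as string is a datatype violation", {
  db <- make_synthetic_db(n_persons = 10L, seed = 8L)
  on.exit(DBI::dbDisconnect(db$con))
  g <- materialize_tml(db$con, fhir_mapping())
  tr <- g$triples
  # retype one Period.start value literal
  starts <- which(tr$predicate == "http://hl7.org/fhir/value" &
                    !is.na(tr$datatype) &
                    tr$datatype == "http://www.w3.org/2001/XMLSchema#dateTime" &
                    grepl("/period/start$", tr$subject))
  g$triples$datatype[starts[1]] <- "http://www.w3.org/2001/XMLSchema#string"
  rep <- validate_graph(g, load_shapes())
  expect_equal(nrow(rep$violations), 1)
  expect_match(rep$violations$reason, "datatype")
  # oracle: direct scan of leaf literals against the declared datatypes
  bad_node <- g$triples$subject[starts[1]]
  expect_equal(rep$violations$node, bad_node)
})
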