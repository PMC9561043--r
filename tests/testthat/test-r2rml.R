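test_that("compilation obeys the size law |maps| = |entries| + |nested|", {
  doc <- fhir_mapping()
  audit <- mapping_audit(doc)
  maps <- compile_tml(doc)
  expect_length(maps, audit$entries + audit$nested_nodes)
  expect_true(all(vapply(maps, function(m)
    !any(vapply(m$poms, function(po) inherits(po$object, "tml_nested"),
                logical(1))), logical(1))))
})

test_that("one nested node yields a parent arc plus a path-suffixed child", {
  doc <- parse_tml(tml_patient_entry())
  maps <- compile_tml(doc)
  # entry has two nested nodes (Resource.id, Patient.birthDate) -> 3 maps
  expect_length(maps, 3)
  child <- maps[[3]]
  expect_match(child$subject_template, "/birthDate$")
  expect_identical(child$logical_table, maps[[1]]$logical_table)
  expect_true(is.na(child$subject_class))
  # the parent points at the child template
  parent_objs <- vapply(maps[[1]]$poms, function(po) {
    if (inherits(po$object, "tml_template")) po$object$template else ""
  }, character(1))
  expect_true(child$subject_template %in% parent_objs)
})

test_that("an entry without nesting compiles to itself", {
  text <- tml_patient_entry(body =
    "    fhir:nodeRole [ rr:constant fhir:treeRoot ]")
  maps <- compile_tml(parse_tml(text))
  expect_length(maps, 1)
  expect_length(maps[[1]]$poms, 1)
  expect_s3_class(maps[[1]]$poms[[1]]$object, "tml_constant")
})

test_that("a depth-3 chain yields 4 maps and matches the direct interpreter", {
  text <- tml_patient_entry(body = paste(
    "    fhir:nodeRole [ rr:constant fhir:treeRoot ] ;",
    "    fhir:Patient.contact [",
    "      fhir:Contact.name [",
    "        fhir:HumanName.family [ fhir:value [ rr:column \"person_id\" ] ]",
    "      ]",
    "    ]", sep = "\n"))
  doc <- parse_tml(text)
  maps <- compile_tml(doc)
  expect_length(maps, 4)
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  load_rows(con, "person", data.frame(
    person_id = 1:3, birth_datetime = paste0(1950:1952, "-01-02T03:04:05")))
  expect_true(graphs_equal(materialize(con, maps),
                           interpret_tml_direct(con, doc)))
})

test_that("duplicate sibling path labels get ordinal segments, no error", {
  text <- tml_patient_entry(body = paste(
    "    fhir:Patient.identifier [",
    "      fhir:Identifier.value [ fhir:value [ rr:column \"person_id\" ] ]",
    "    ] ;",
    "    fhir:Patient.identifier [",
    "      fhir:Identifier.value [ fhir:value [ rr:column \"birth_date\" ] ]",
    "    ]", sep = "\n"))
  maps <- compile_tml(parse_tml(text))
  templates <- vapply(maps, function(m) m$subject_template, character(1))
  expect_true(any(grepl("/identifier/0$", templates)))
  expect_true(any(grepl("/identifier/1$", templates)))
})

test_that("R2RML serialization round-trips and reaches a fixpoint", {
  maps <- compile_tml(fhir_mapping())
  text1 <- serialize_r2rml(maps)
  # a generic Turtle parser accepts the document
  expect_silent(turtle_parse(text1))
  back <- parse_r2rml(text1)
  expect_length(back, length(maps))
  for (i in seq_along(maps)) {
    expect_equal(back[[i]]$subject_template, maps[[i]]$subject_template)
    expect_equal(back[[i]]$subject_class, maps[[i]]$subject_class)
    expect_equal(back[[i]]$logical_table, maps[[i]]$logical_table)
    expect_equal(back[[i]]$poms, maps[[i]]$poms, info = paste("map", i))
  }
  expect_identical(serialize_r2rml(back), text1)
  expect_match(serialize_r2rml(list()), "@prefix rr:")
})

test_that("compiled maps and direct interpretation agree on a full database", {
  db <- make_synthetic_db(n_persons = 15L,
                          planted = c(Q1 = 2L, Q2 = 1L, Q3 = 1L,
                                      Q4 = 1L, Q5 = 1L), seed = 9L)
  on.exit(DBI::dbDisconnect(db$con))
  doc <- fhir_mapping()
  expect_true(graphs_equal(materialize(db$con, compile_tml(doc)),
                           interpret_tml_direct(db$con, doc)))
})
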