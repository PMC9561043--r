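test_that("a person-to-Patient entry parses into the expected structure", {
  doc <- parse_tml(tml_patient_entry())
  expect_length(doc$entries, 1)
  e <- doc$entries[[1]]
  expect_match(e$logical_table, "FROM person")
  expect_match(e$subject_template, "\\{person_id\\}", perl = TRUE)
  expect_equal(e$subject_class, "http://hl7.org/fhir/Patient")
  # document order of the object tree is preserved
  preds <- vapply(e$object_tree, function(po) po$predicate, character(1))
  expect_equal(basename(preds),
               c("nodeRole", "Resource.id", "Patient.birthDate"))
  id_node <- e$object_tree[[2]]$object
  expect_s3_class(id_node, "tml_nested")
  expect_s3_class(id_node$children[[1]]$object, "tml_column")
  expect_equal(id_node$children[[1]]$object$column, "person_id")
})

test_that("subject class is inferred from the template path when absent", {
  text <- sub(" ;\n                  rr:class fhir:Patient", "",
              tml_patient_entry(), fixed = TRUE)
  doc <- parse_tml(text)
  expect_equal(doc$entries[[1]]$subject_class, "http://hl7.org/fhir/Patient")
})

test_that("a prefix-only document has zero entries", {
  doc <- parse_tml(TML_PREFIXES)
  expect_length(doc$entries, 0)
})

test_that("structural defects are rejected at parse time", {
  bad_ph <- sub("rr:column \"person_id\"", "rr:column \"person_id\"",
                sub("\\{person_id\\}", "{unknown_col}", tml_patient_entry()))
  expect_error(parse_tml(bad_ph), "\\{unknown_col\\}")
  no_sm <- sub("rr:subjectMap \\[[^]]*\\] ;", "", tml_patient_entry())
  expect_error(parse_tml(no_sm), "rr:subjectMap")
  no_lt <- paste0(TML_PREFIXES, "\n\nmap:X rr:subjectMap [",
                  " rr:template \"http://e.org/X/{id}\" ] .")
  expect_error(parse_tml(no_lt), "rr:logicalTable")
})

test_that("serialization round-trips structurally and is order-stable", {
  doc <- fhir_mapping()
  text1 <- serialize_tml(doc)
  doc2 <- parse_tml(text1)
  expect_equal(length(doc2$entries), length(doc$entries))
  for (i in seq_along(doc$entries)) {
    expect_equal(doc2$entries[[i]]$object_tree, doc$entries[[i]]$object_tree,
                 info = paste("entry", i))
    expect_equal(doc2$entries[[i]]$subject_template,
                 doc$entries[[i]]$subject_template)
  }
  # fixpoint from the second pass
  expect_identical(serialize_tml(doc2), text1)
})

test_that("validate_tml passes the shipped mapping and flags defects", {
  expect_equal(nrow(validate_tml(fhir_mapping())), 0)

  typo <- sub("FROM person", "FROM persons", tml_patient_entry(), fixed = TRUE)
  issues <- validate_tml(parse_tml(typo))
  expect_true(any(grepl("unknown table 'persons'", issues$message)))

  deep <- tml_patient_entry(body = paste0(
    "    fhir:a [ fhir:b [ fhir:c [ fhir:d [ fhir:e [ fhir:f [ fhir:g [",
    " fhir:value [ rr:column \"person_id\" ] ] ] ] ] ] ] ]"))
  issues <- validate_tml(parse_tml(deep))
  expect_true(any(grepl("exceeds 6", issues$message)))

  undeclared <- tml_patient_entry(body = paste0(
    "    <http://other.org/ns#pred> [ fhir:value [",
    " rr:column \"person_id\" ] ]"))
  issues <- validate_tml(parse_tml(undeclared))
  expect_true(any(grepl("not in a declared namespace", issues$message)))
})
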