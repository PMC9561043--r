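test_that("schema creation yields the declared tables and is idempotent", {
  con <- omop_connect()
  on.exit(DBI::dbDisconnect(con))
  schema <- create_schema(con)
  expect_setequal(DBI::dbListTables(con),
                  c(names(omop_schema()$tables), "coding_system_map"))
  expect_true(all(c("person_id", "gender_concept_id", "birth_datetime",
                    "year_of_birth", "month_of_birth", "day_of_birth")
                  %in% DBI::dbListFields(con, "person")))
  expect_true(all(c("visit_start_date", "visit_start_datetime",
                    "visit_end_date", "visit_end_datetime",
                    "visit_concept_id")
                  %in% DBI::dbListFields(con, "visit_occurrence")))
  # re-run: identical schema, no duplicates, no error
  again <- create_schema(con)
  expect_identical(names(again$tables), names(schema$tables))
  expect_setequal(DBI::dbListTables(con),
                  c(names(omop_schema()$tables), "coding_system_map"))
})

test_that("an incompatible pre-existing table raises a schema conflict", {
  con <- omop_connect()
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE person (not_person_id INTEGER)")
  expect_error(create_schema(con), "schema conflict.*person")
})

test_that("load_rows counts inserts and stores absent fields as SQL NULL", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  n <- load_rows(con, "person", list(
    list(person_id = 1L, gender_concept_id = 8507L,
         birth_datetime = "1960-01-02T03:04:05"),
    list(person_id = 2L, gender_concept_id = 8532L),
    list(person_id = 3L)))
  expect_equal(n, 3)
  got <- DBI::dbGetQuery(con, "SELECT * FROM person ORDER BY person_id")
  expect_true(is.na(got$birth_datetime[2]))
  expect_true(is.na(got$gender_concept_id[3]))
  expect_equal(DBI::dbGetQuery(con,
    "SELECT COUNT(*) AS n FROM person WHERE birth_datetime IS NULL")$n, 2)
  # round trip is order-insensitive and lossless
  expect_setequal(got$person_id, c(1L, 2L, 3L))
})

test_that("load_rows rejects unknown targets and bad values", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  expect_error(load_rows(con, "persons", list(list(person_id = 1))),
               "unknown table")
  expect_error(load_rows(con, "person", list(list(foo = 1))),
               "unknown column")
  expect_error(
    load_rows(con, "person", list(list(person_id = 1L, year_of_birth = "x"))),
    "row 1")
})

test_that("vocabulary seeding enforces unique concept ids", {
  con <- omop_connect()
  on.exit(DBI::dbDisconnect(con))
  create_schema(con)
  n <- seed_vocabulary(con)
  expect_gte(n, 7)
  ids <- DBI::dbGetQuery(con, "SELECT concept_id FROM concept")$concept_id
  expect_true(all(c(8507, 9201, 262) %in% ids))
  expect_error(seed_vocabulary(con), "duplicate concept_id")
  dup <- default_vocabulary()[c(1, 1), ]
  con2 <- omop_connect()
  on.exit(DBI::dbDisconnect(con2), add = TRUE)
  create_schema(con2)
  expect_error(seed_vocabulary(con2, dup), "duplicate concept_id 8507")
  expect_equal(seed_vocabulary(con2, default_vocabulary()[0, ]), 0)
})

test_that("CSV fixture loading maps empty fields to NULL", {
  con <- make_db()
  on.exit(DBI::dbDisconnect(con))
  path <- tempfile(fileext = ".csv")
  writeLines(c("person_id,gender_concept_id,birth_datetime",
               "1,8507,1950-05-06T07:08:09",
               "2,,"), path)
  expect_equal(load_table_csv(con, "person", path), 2)
  got <- DBI::dbGetQuery(con, "SELECT * FROM person WHERE person_id = 2")
  expect_true(is.na(got$gender_concept_id))
  expect_true(is.na(got$birth_datetime))
})
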