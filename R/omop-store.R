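# OMOP CDM v5.x table subset: schema definition, creation, loading, seeding.
#
# The subset covers the columns of the v5.3/v5.4 intersection actually
# referenced by the shipped mapping set; redundant date parts (year_of_birth,
# visit_start_date, ...) are present but unmapped. Datetimes are stored as
# ISO-8601 text with seconds precision ("YYYY-MM-DDTHH:MM:SS"), dates as
# ISO-8601 date text, so cross-engine comparison semantics are unambiguous.

#' OMOP CDM table subset definition
#'
#' @return An object of class `omop_schema`: a list of table definitions,
#'   each with `columns` (named character vector, column -> SQL type),
#'   `primary_key`, and `foreign_keys` (named character vector,
#'   column -> "table.column").
#' @export
omop_schema <- function() {
  tdef <- function(columns, primary_key = NULL, foreign_keys = character(0)) {
    list(columns = columns, primary_key = primary_key,
         foreign_keys = foreign_keys)
  }
  tables <- list(
    person = tdef(
      c(person_id = "INTEGER", gender_concept_id = "INTEGER",
        year_of_birth = "INTEGER", month_of_birth = "INTEGER",
        day_of_birth = "INTEGER", birth_datetime = "DATETIME",
        race_concept_id = "INTEGER", ethnicity_concept_id = "INTEGER",
        location_id = "INTEGER", provider_id = "INTEGER",
        care_site_id = "INTEGER", person_source_value = "VARCHAR"),
      "person_id",
      c(gender_concept_id = "concept.concept_id",
        location_id = "location.location_id",
        provider_id = "provider.provider_id",
        care_site_id = "care_site.care_site_id")),
    visit_occurrence = tdef(
      c(visit_occurrence_id = "INTEGER", person_id = "INTEGER",
        visit_concept_id = "INTEGER", visit_start_date = "DATE",
        visit_start_datetime = "DATETIME", visit_end_date = "DATE",
        visit_end_datetime = "DATETIME", visit_type_concept_id = "INTEGER",
        provider_id = "INTEGER", care_site_id = "INTEGER"),
      "visit_occurrence_id",
      c(person_id = "person.person_id",
        visit_concept_id = "concept.concept_id")),
    condition_occurrence = tdef(
      c(condition_occurrence_id = "INTEGER", person_id = "INTEGER",
        condition_concept_id = "INTEGER", condition_start_date = "DATE",
        condition_start_datetime = "DATETIME",
        condition_type_concept_id = "INTEGER",
        visit_occurrence_id = "INTEGER"),
      "condition_occurrence_id",
      c(person_id = "person.person_id",
        condition_concept_id = "concept.concept_id")),
    drug_exposure = tdef(
      c(drug_exposure_id = "INTEGER", person_id = "INTEGER",
        drug_concept_id = "INTEGER", drug_exposure_start_date = "DATE",
        drug_exposure_start_datetime = "DATETIME",
        drug_exposure_end_date = "DATE",
        drug_exposure_end_datetime = "DATETIME",
        drug_type_concept_id = "INTEGER", quantity = "NUMERIC",
        visit_occurrence_id = "INTEGER"),
      "drug_exposure_id",
      c(person_id = "person.person_id",
        drug_concept_id = "concept.concept_id")),
    procedure_occurrence = tdef(
      c(procedure_occurrence_id = "INTEGER", person_id = "INTEGER",
        procedure_concept_id = "INTEGER", procedure_date = "DATE",
        procedure_datetime = "DATETIME",
        procedure_type_concept_id = "INTEGER",
        visit_occurrence_id = "INTEGER"),
      "procedure_occurrence_id",
      c(person_id = "person.person_id",
        procedure_concept_id = "concept.concept_id")),
    measurement = tdef(
      c(measurement_id = "INTEGER", person_id = "INTEGER",
        measurement_concept_id = "INTEGER", measurement_date = "DATE",
        measurement_datetime = "DATETIME",
        measurement_type_concept_id = "INTEGER",
        value_as_number = "NUMERIC", unit_concept_id = "INTEGER",
        unit_source_value = "VARCHAR", visit_occurrence_id = "INTEGER"),
      "measurement_id",
      c(person_id = "person.person_id",
        measurement_concept_id = "concept.concept_id")),
    care_site = tdef(
      c(care_site_id = "INTEGER", care_site_name = "VARCHAR",
        location_id = "INTEGER"),
      "care_site_id",
      c(location_id = "location.location_id")),
    location = tdef(
      c(location_id = "INTEGER", address_1 = "VARCHAR", city = "VARCHAR",
        state = "VARCHAR", zip = "VARCHAR"),
      "location_id"),
    provider = tdef(
      c(provider_id = "INTEGER", provider_name = "VARCHAR", npi = "VARCHAR",
        specialty_concept_id = "INTEGER", care_site_id = "INTEGER"),
      "provider_id"),
    concept = tdef(
      c(concept_id = "INTEGER", concept_name = "VARCHAR",
        domain_id = "VARCHAR", vocabulary_id = "VARCHAR",
        concept_class_id = "VARCHAR", standard_concept = "VARCHAR",
        concept_code = "VARCHAR"),
      "concept_id"),
    concept_relationship = tdef(
      c(concept_id_1 = "INTEGER", concept_id_2 = "INTEGER",
        relationship_id = "VARCHAR")),
    concept_ancestor = tdef(
      c(ancestor_concept_id = "INTEGER", descendant_concept_id = "INTEGER",
        min_levels_of_separation = "INTEGER",
        max_levels_of_separation = "INTEGER"))
  )
  structure(list(tables = tables), class = "omop_schema")
}

#' @export
print.omop_schema <- function(x, ...) {
  cat("<omop_schema> ", length(x$tables), " tables: ",
      paste(names(x$tables), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Auxiliary engine table holding the vocabulary_id -> preferred Coding System
# URI translation; not part of the OMOP table set.
CODING_SYSTEM_TABLE <- "coding_system_map"

sql_type <- function(t) {
  switch(t, INTEGER = "INTEGER", NUMERIC = "NUMERIC", VARCHAR = "TEXT",
         DATE = "TEXT", DATETIME = "TEXT",
         stop("unknown SQL type ", t, call. = FALSE))
}

table_ddl <- function(name, def) {
  cols <- vapply(names(def$columns), function(cn) {
    paste0(cn, " ", sql_type(def$columns[[cn]]),
           if (identical(def$primary_key, cn)) " PRIMARY KEY" else "")
  }, character(1))
  paste0("CREATE TABLE ", name, " (\n  ", paste(cols, collapse = ",\n  "),
         "\n);")
}

#' Render the DDL for the OMOP subset
#'
#' @param schema An `omop_schema`; defaults to [omop_schema()].
#' @return Character vector of CREATE TABLE statements (one per table, the
#'   auxiliary coding-system translation table last).
#' @export
omop_ddl <- function(schema = omop_schema()) {
  c(vapply(names(schema$tables),
           function(nm) table_ddl(nm, schema$tables[[nm]]), character(1),
           USE.NAMES = FALSE),
    paste0("CREATE TABLE ", CODING_SYSTEM_TABLE,
           " (\n  vocabulary_id TEXT PRIMARY KEY,\n  system_uri TEXT\n);"))
}

#' Open an OMOP database connection
#'
#' @param path SQLite database file, or `":memory:"` (default) for an
#'   in-memory database.
#' @return A `DBIConnection`.
#' @export
omop_connect <- function(path = ":memory:") {
  DBI::dbConnect(RSQLite::SQLite(), path)
}

#' Create the OMOP CDM table subset
#'
#' Creates the 12 tables of the subset plus the auxiliary coding-system
#' translation table (seeded from [translate_system()]'s 13-entry table).
#' Idempotent: re-running against a database already holding a compatible
#' schema is a no-op; an existing table with missing columns raises a
#' schema-conflict error naming the table.
#'
#' @param con A `DBIConnection` from [omop_connect()].
#' @param schema An `omop_schema`; defaults to [omop_schema()].
#' @return The schema descriptor, invisibly compatible with the database.
#' @export
create_schema <- function(con, schema = omop_schema()) {
  existing <- DBI::dbListTables(con)
  for (nm in names(schema$tables)) {
    if (nm %in% existing) {
      have <- DBI::dbListFields(con, nm)
      want <- names(schema$tables[[nm]]$columns)
      if (!all(want %in% have)) {
        stop("schema conflict: existing table '", nm, "' lacks column(s) ",
             paste(setdiff(want, have), collapse = ", "), call. = FALSE)
      }
    } else {
      DBI::dbExecute(con, table_ddl(nm, schema$tables[[nm]]))
    }
  }
  if (!CODING_SYSTEM_TABLE %in% existing) {
    DBI::dbExecute(con, utils::tail(omop_ddl(schema), 1))
    sysmap <- coding_system_table()
    DBI::dbAppendTable(con, CODING_SYSTEM_TABLE, sysmap)
  }
  invisible(schema)
}

#' Insert records into an OMOP table
#'
#' Record fields must be a subset of the table's columns; absent fields are
#' stored as SQL NULL (never as empty strings).
#'
#' @param con A `DBIConnection`.
#' @param table Table name.
#' @param rows A data frame, or a list of named lists/vectors.
#' @return Number of rows inserted.
#' @export
load_rows <- function(con, table, rows) {
  schema <- omop_schema()
  if (!table %in% c(names(schema$tables), CODING_SYSTEM_TABLE)) {
    stop("load error: unknown table '", table, "'", call. = FALSE)
  }
  if (!is.data.frame(rows)) {
    all_cols <- unique(unlist(lapply(rows, names)))
    rows <- do.call(rbind, lapply(rows, function(r) {
      r <- lapply(r, function(v) if (is.null(v)) NA else v)
      miss <- setdiff(all_cols, names(r))
      r[miss] <- NA
      as.data.frame(r[all_cols], stringsAsFactors = FALSE)
    }))
  }
  if (is.null(rows) || nrow(rows) == 0) return(0L)
  cols <- DBI::dbListFields(con, table)
  unknown <- setdiff(names(rows), cols)
  if (length(unknown) > 0) {
    stop("load error: unknown column(s) ", paste(unknown, collapse = ", "),
         " for table '", table, "'", call. = FALSE)
  }
  typed <- coerce_columns(rows, schema$tables[[table]]$columns, table)
  DBI::dbAppendTable(con, table, typed)
  nrow(typed)
}

coerce_columns <- function(rows, columns, table) {
  for (cn in names(rows)) {
    declared <- columns[[cn]]
    if (is.null(declared)) next
    v <- rows[[cn]]
    if (declared %in% c("INTEGER", "NUMERIC")) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0) {
        stop("load error: value '", v[bad[1]], "' in row ", bad[1],
             " not coercible to ", declared, " for ", table, ".", cn,
             call. = FALSE)
      }
      rows[[cn]] <- if (declared == "INTEGER") as.integer(num) else num
    } else {
      rows[[cn]] <- as.character(v)
    }
  }
  rows
}

#' Load a table from a CSV fixture
#'
#' Header row gives column names; empty fields become NULL.
#'
#' @param con A `DBIConnection`.
#' @param table Table name.
#' @param path CSV file path.
#' @return Number of rows inserted.
#' @export
load_table_csv <- function(con, table, path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  df[df == ""] <- NA
  load_rows(con, table, df)
}

#' Default seed vocabulary
#'
#' A miniature OMOP vocabulary sufficient for the mapping set and the five
#' demonstration queries: administrative gender (8507 male / 8532 female),
#' inpatient visit concepts 9201 and 262, an outpatient visit concept, one
#' Alzheimer's disease condition, one delivery procedure, one trazodone drug,
#' one HbA1c measurement, and disjoint background concepts. Codes are
#' realistic SNOMED/RxNorm/LOINC values but the table is synthetic package
#' data, not an OHDSI vocabulary download.
#'
#' @return Data frame matching the `concept` table columns.
#' @export
default_vocabulary <- function() {
  con <- function(id, name, domain, vocab, cls, code)
    data.frame(concept_id = id, concept_name = name, domain_id = domain,
               vocabulary_id = vocab, concept_class_id = cls,
               standard_concept = "S", concept_code = code,
               stringsAsFactors = FALSE)
  rbind(
    con(8507L,    "MALE",                      "Gender",      "Gender", "Gender",         "M"),
    con(8532L,    "FEMALE",                    "Gender",      "Gender", "Gender",         "F"),
    con(9201L,    "Inpatient Visit",           "Visit",       "Visit",  "Visit",          "IP"),
    con(262L,     "Emergency Room and Inpatient Visit", "Visit", "Visit", "Visit",        "ERIP"),
    con(9202L,    "Outpatient Visit",          "Visit",       "Visit",  "Visit",          "OP"),
    con(378419L,  "Alzheimer's disease",       "Condition",   "SNOMED", "Clinical Finding", "26929004"),
    con(320128L,  "Essential hypertension",    "Condition",   "SNOMED", "Clinical Finding", "59621000"),
    con(4125611L, "Delivery procedure",        "Procedure",   "SNOMED", "Procedure",      "236973005"),
    con(4301351L, "Appendectomy",              "Procedure",   "SNOMED", "Procedure",      "80146002"),
    con(738156L,  "trazodone",                 "Drug",        "RxNorm", "Ingredient",     "10737"),
    con(1125315L, "acetaminophen",             "Drug",        "RxNorm", "Ingredient",     "161"),
    con(3004410L, "Hemoglobin A1c/Hemoglobin.total in Blood", "Measurement", "LOINC", "Lab Test", "4548-4"),
    con(3000483L, "Glucose [Mass/volume] in Blood", "Measurement", "LOINC", "Lab Test",   "2345-7")
  )
}

# concept_ids of the planted query criteria, keyed for the demo suite
#' Concept ids used by the demonstration queries
#' @return Named integer list: `male`, `inpatient`, `alzheimer`, `delivery`,
#'   `trazodone`, `hba1c`, plus disjoint background concepts.
#' @export
query_concepts <- function() {
  list(male = 8507L, female = 8532L, inpatient = c(9201L, 262L),
       outpatient = 9202L, alzheimer = 378419L, delivery = 4125611L,
       trazodone = 738156L, hba1c = 3004410L,
       background_condition = 320128L, background_procedure = 4301351L,
       background_drug = 1125315L, background_measurement = 3000483L)
}

#' Seed the concept table
#'
#' @param con A `DBIConnection` with the schema created.
#' @param vocab Data frame of concept rows; defaults to
#'   [default_vocabulary()]. Pass a zero-row frame to seed nothing.
#' @return Number of concepts inserted.
#' @export
seed_vocabulary <- function(con, vocab = default_vocabulary()) {
  if (nrow(vocab) == 0) return(0L)
  dup <- vocab$concept_id[duplicated(vocab$concept_id)]
  if (length(dup) > 0) {
    stop("duplicate concept_id ", paste(unique(dup), collapse = ", "),
         " in seed vocabulary", call. = FALSE)
  }
  present <- DBI::dbGetQuery(con, "SELECT concept_id FROM concept")$concept_id
  clash <- intersect(vocab$concept_id, present)
  if (length(clash) > 0) {
    stop("duplicate concept_id ", paste(clash, collapse = ", "),
         " already present in concept table", call. = FALSE)
  }
  load_rows(con, "concept", vocab)
}

# Dump every OMOP table to a named list of data frames (CSV-exportable).
#' Export the database content
#' @param con A `DBIConnection`.
#' @param dir Optional directory; when given, one CSV per table is written.
#' @return Named list of data frames, invisibly when `dir` is given.
#' @export
dump_database <- function(con, dir = NULL) {
  out <- lapply(names(omop_schema()$tables), function(nm) {
    df <- DBI::dbGetQuery(con, paste0("SELECT * FROM ", nm))
    df[do.call(order, c(as.list(df), list(method = "radix"))), , drop = FALSE]
  })
  names(out) <- names(omop_schema()$tables)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, na = "")
    }
    return(invisible(out))
  }
  out
}
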