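# Seeded synthetic OMOP generator with planted, known-size cohorts.
#
# The generator emulates a MIMIC-like OMOP instance at desk scale: event dates
# fall in 2001-2012, birth dates in 1930-2000, and each of the five
# demonstration-query cohorts is planted by construction, so faithfulness
# tests have a third, generation-time oracle next to the SQL and SPARQL
# cohorts. Background events use concepts disjoint from the query concepts;
# deliberate near-miss rows (a 5.000-day male inpatient stay, an HbA1c below
# 10) exercise the strict ">" of Q1 and the ">=" of Q5.

#' Synthetic dataset configuration
#'
#' @param n_persons Number of persons to generate.
#' @param planted Named integer vector of cohort sizes for queries
#'   `Q1`..`Q5`. Planted members are disjoint across queries, so their sizes
#'   must sum to at most `n_persons`.
#' @param background_rates Named numeric vector: expected background events
#'   per person for `visit`, `condition`, `drug`, `procedure`, `measurement`.
#' @param missingness Named numeric vector of probabilities, names of the
#'   form `"table.column"`; the column is nulled with that probability.
#'   Primary keys, `person_id` and `*_concept_id` columns cannot be targeted.
#' @param seed Integer seed; the same (config, seed) yields byte-identical
#'   database content.
#' @param address_fraction,provider_fraction Fraction of persons holding a
#'   `location_id` / `provider_id` reference (the rest are NULL, which the
#'   materializer must suppress).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_persons = 100L,
                             planted = c(Q1 = 7L, Q2 = 5L, Q3 = 2L,
                                         Q4 = 9L, Q5 = 4L),
                             background_rates = c(visit = 1, condition = 1,
                                                  drug = 1, procedure = 0.5,
                                                  measurement = 1),
                             missingness = NULL,
                             seed = 42L,
                             address_fraction = 0.3,
                             provider_fraction = 0.3) {
  qids <- paste0("Q", 1:5)
  full <- stats::setNames(integer(5), qids)
  full[names(planted)] <- as.integer(planted)
  planted <- full
  if (any(planted < 0)) stop("config error: negative planted size",
                             call. = FALSE)
  if (any(planted > n_persons)) {
    stop("config error: planted cohort size exceeds n_persons", call. = FALSE)
  }
  if (sum(planted) > n_persons) {
    stop("config error: planted cohorts are disjoint; sizes must sum to ",
         "at most n_persons", call. = FALSE)
  }
  if (!is.null(missingness)) {
    is_pk <- vapply(strsplit(names(missingness), ".", fixed = TRUE),
                    function(p) {
                      def <- omop_schema()$tables[[p[1]]]
                      !is.null(def) && identical(def$primary_key, p[2])
                    }, logical(1))
    if (any(is_pk) ||
        any(grepl("\\.person_id$|_concept_id$", names(missingness)))) {
      stop("config error: unsatisfiable missingness (required key column)",
           call. = FALSE)
    }
  }
  structure(list(n_persons = as.integer(n_persons), planted = planted,
                 background_rates = background_rates,
                 missingness = missingness, seed = as.integer(seed),
                 address_fraction = address_fraction,
                 provider_fraction = provider_fraction),
            class = "synthetic_config")
}

iso_datetime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
iso_date <- function(x) format(x, "%Y-%m-%d", tz = "UTC")

rand_datetime <- function(n, from, to) {
  a <- as.numeric(as.POSIXct(from, tz = "UTC"))
  b <- as.numeric(as.POSIXct(to, tz = "UTC"))
  as.POSIXct(floor(a + stats::runif(n) * (b - a)), origin = "1970-01-01",
             tz = "UTC")
}

#' Generate a synthetic OMOP dataset with planted cohorts
#'
#' Fills a schema-created, vocabulary-seeded database with `n_persons`
#' persons, their visits and clinical events. After loading, the five cohorts
#' are recomputed by a brute-force scan of the generated frames (independent
#' of SQL and SPARQL); accidental qualifiers among background persons are
#' repaired and the scan repeated, so the returned ground truth is exact by
#' construction.
#'
#' @param config A [synthetic_config()].
#' @param con A `DBIConnection` with schema created and vocabulary seeded.
#' @return An object of class `ckg_ground_truth`: list with `cohorts` (named
#'   list `Q1`..`Q5` of person_id vectors), `config`, and `seed`.
#' @export
generate_synthetic <- function(config, con) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!"concept" %in% DBI::dbListTables(con)) {
    stop("schema must be created before generating", call. = FALSE)
  }
  qc <- query_concepts()
  have <- DBI::dbGetQuery(con, "SELECT concept_id FROM concept")$concept_id
  if (!all(c(qc$male, qc$inpatient) %in% have)) {
    stop("vocabulary must be seeded before generating (seed_vocabulary)",
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_persons
  pl <- config$planted
  ids <- seq_len(n)
  bounds <- cumsum(c(0, pl))
  member <- lapply(1:5, function(k) ids[seq_len(pl[k]) + bounds[k]])
  names(member) <- names(pl)
  background <- ids[ids > bounds[6]]
  near_q1 <- utils::head(background, 2L)   # male inpatient stays <= 5 days
  near_q5 <- utils::head(setdiff(background, near_q1), 2L)  # HbA1c < 10

  # --- health system tables -------------------------------------------------
  locations <- data.frame(
    location_id = 1:5,
    address_1 = paste(1:5 * 100, "Main St"),
    city = c("Boston", "Cambridge", "Somerville", "Quincy", "Newton"),
    state = "MA",
    zip = sprintf("021%02d", 1:5), stringsAsFactors = FALSE)
  care_sites <- data.frame(
    care_site_id = 1:3,
    care_site_name = paste("Care site", 1:3),
    location_id = 1:3, stringsAsFactors = FALSE)
  providers <- data.frame(
    provider_id = 1:5,
    provider_name = paste("Provider", LETTERS[1:5]),
    npi = sprintf("1%09d", 1:5),
    specialty_concept_id = NA_integer_,
    care_site_id = rep(1:3, length.out = 5), stringsAsFactors = FALSE)

  # --- person ---------------------------------------------------------------
  gender <- sample(c(qc$male, qc$female), n, replace = TRUE)
  gender[member$Q1] <- qc$male
  gender[near_q1] <- qc$male
  gender[member$Q3] <- qc$female
  birth <- rand_datetime(n, "1930-01-01 00:00:00", "2000-12-31 23:59:59")
  has_addr <- stats::runif(n) < config$address_fraction
  has_prov <- stats::runif(n) < config$provider_fraction
  person <- data.frame(
    person_id = ids,
    gender_concept_id = gender,
    year_of_birth = as.integer(format(birth, "%Y", tz = "UTC")),
    month_of_birth = as.integer(format(birth, "%m", tz = "UTC")),
    day_of_birth = as.integer(format(birth, "%d", tz = "UTC")),
    birth_datetime = iso_datetime(birth),
    race_concept_id = 0L, ethnicity_concept_id = 0L,
    location_id = ifelse(has_addr, sample(locations$location_id, n,
                                          replace = TRUE), NA_integer_),
    provider_id = ifelse(has_prov, sample(providers$provider_id, n,
                                          replace = TRUE), NA_integer_),
    care_site_id = NA_integer_,
    person_source_value = sprintf("SYN-%05d", ids),
    stringsAsFactors = FALSE)

  # --- visits ---------------------------------------------------------------
  visit_person <- integer(0); visit_concept <- integer(0)
  visit_start <- .POSIXct(numeric(0), tz = "UTC"); visit_days <- numeric(0)
  add_visit <- function(pid, concept, start, days) {
    visit_person <<- c(visit_person, pid)
    visit_concept <<- c(visit_concept, concept)
    visit_start <<- c(visit_start, start)
    visit_days <<- c(visit_days, days)
  }
  for (pid in member$Q1) {
    add_visit(pid, sample(qc$inpatient, 1L),
              rand_datetime(1, "2001-01-01 00:00:00", "2012-06-30 23:59:59"),
              stats::runif(1, 5.5, 55))
  }
  if (length(near_q1) >= 1) {
    add_visit(near_q1[1], qc$inpatient[1],
              rand_datetime(1, "2001-01-01 00:00:00", "2012-06-30 23:59:59"),
              5)  # exactly 5.000 days: excluded by the strict inequality
  }
  if (length(near_q1) >= 2) {
    add_visit(near_q1[2], qc$inpatient[2],
              rand_datetime(1, "2001-01-01 00:00:00", "2012-06-30 23:59:59"),
              stats::runif(1, 0.5, 4.5))
  }
  for (pid in setdiff(ids, c(member$Q1, near_q1))) {
    add_visit(pid, qc$outpatient,
              rand_datetime(1, "2001-01-01 00:00:00", "2012-06-30 23:59:59"),
              stats::runif(1, 0.05, 0.4))
  }
  extra <- stats::rpois(n, config$background_rates[["visit"]] * 0.3)
  for (pid in ids[extra > 0]) {
    for (i in seq_len(extra[pid])) {
      add_visit(pid, qc$outpatient,
                rand_datetime(1, "2001-01-01 00:00:00", "2012-06-30 23:59:59"),
                stats::runif(1, 0.05, 0.4))
    }
  }
  visit_end <- visit_start + round(visit_days * 86400)
  visits <- data.frame(
    visit_occurrence_id = seq_along(visit_person),
    person_id = visit_person,
    visit_concept_id = visit_concept,
    visit_start_date = iso_date(visit_start),
    visit_start_datetime = iso_datetime(visit_start),
    visit_end_date = iso_date(visit_end),
    visit_end_datetime = iso_datetime(visit_end),
    visit_type_concept_id = 44818517L,
    provider_id = NA_integer_, care_site_id = NA_integer_,
    stringsAsFactors = FALSE)
  first_visit <- visits$visit_occurrence_id[match(ids, visits$person_id)]

  event_dt <- function(k) rand_datetime(k, "2001-01-01 00:00:00",
                                        "2012-12-30 23:59:59")
  n_bg <- function(rate) stats::rpois(n, rate)

  # --- conditions -----------------------------------------------------------
  cond_pid <- c(member$Q2, rep(ids, n_bg(config$background_rates[["condition"]])))
  cond_cid <- c(rep(qc$alzheimer, length(member$Q2)),
                rep(qc$background_condition,
                    length(cond_pid) - length(member$Q2)))
  cond_when <- event_dt(length(cond_pid))
  conditions <- data.frame(
    condition_occurrence_id = seq_along(cond_pid),
    person_id = cond_pid, condition_concept_id = cond_cid,
    condition_start_date = iso_date(cond_when),
    condition_start_datetime = iso_datetime(cond_when),
    condition_type_concept_id = 32020L,
    visit_occurrence_id = first_visit[cond_pid], stringsAsFactors = FALSE)

  # --- drugs ----------------------------------------------------------------
  drug_pid <- c(member$Q4, rep(ids, n_bg(config$background_rates[["drug"]])))
  drug_cid <- c(rep(qc$trazodone, length(member$Q4)),
                rep(qc$background_drug, length(drug_pid) - length(member$Q4)))
  drug_start <- event_dt(length(drug_pid))
  drug_end <- drug_start + round(stats::runif(length(drug_pid), 1, 30)) * 86400
  drugs <- data.frame(
    drug_exposure_id = seq_along(drug_pid),
    person_id = drug_pid, drug_concept_id = drug_cid,
    drug_exposure_start_date = iso_date(drug_start),
    drug_exposure_start_datetime = iso_datetime(drug_start),
    drug_exposure_end_date = iso_date(drug_end),
    drug_exposure_end_datetime = iso_datetime(drug_end),
    drug_type_concept_id = 38000177L,
    quantity = round(stats::runif(length(drug_pid), 1, 90)),
    visit_occurrence_id = first_visit[drug_pid], stringsAsFactors = FALSE)

  # --- procedures -----------------------------------------------------------
  proc_pid <- c(member$Q3, rep(ids, n_bg(config$background_rates[["procedure"]])))
  proc_cid <- c(rep(qc$delivery, length(member$Q3)),
                rep(qc$background_procedure,
                    length(proc_pid) - length(member$Q3)))
  proc_when <- event_dt(length(proc_pid))
  procedures <- data.frame(
    procedure_occurrence_id = seq_along(proc_pid),
    person_id = proc_pid, procedure_concept_id = proc_cid,
    procedure_date = iso_date(proc_when),
    procedure_datetime = iso_datetime(proc_when),
    procedure_type_concept_id = 38000275L,
    visit_occurrence_id = first_visit[proc_pid], stringsAsFactors = FALSE)

  # --- measurements ---------------------------------------------------------
  q5 <- member$Q5
  hba1c_val <- if (length(q5) > 0) {
    c(10, round(stats::runif(length(q5) - 1, 10.1, 15), 1))  # one exact 10.0
  } else numeric(0)
  near_val <- round(stats::runif(length(near_q5), 4, 9.9), 1)
  bg_pid <- rep(ids, n_bg(config$background_rates[["measurement"]]))
  meas_pid <- c(q5, near_q5, bg_pid)
  meas_cid <- c(rep(qc$hba1c, length(q5) + length(near_q5)),
                rep(qc$background_measurement, length(bg_pid)))
  meas_val <- c(hba1c_val, near_val,
                round(stats::runif(length(bg_pid), 70, 200), 1))
  meas_unit <- c(rep("%", length(q5) + length(near_q5)),
                 rep("mg/dL", length(bg_pid)))
  meas_when <- event_dt(length(meas_pid))
  measurements <- data.frame(
    measurement_id = seq_along(meas_pid),
    person_id = meas_pid, measurement_concept_id = meas_cid,
    measurement_date = iso_date(meas_when),
    measurement_datetime = iso_datetime(meas_when),
    measurement_type_concept_id = 44818702L,
    value_as_number = meas_val, unit_concept_id = NA_integer_,
    unit_source_value = meas_unit,
    visit_occurrence_id = first_visit[meas_pid], stringsAsFactors = FALSE)

  # --- vocabulary relationship tables --------------------------------------
  # OMOP convention: standard concepts map to themselves and are their own
  # zero-level ancestors; these rows give the ConceptMap entries content.
  clinical <- DBI::dbGetQuery(con,
    "SELECT concept_id FROM concept WHERE domain_id IN
       ('Condition', 'Procedure', 'Drug', 'Measurement')
     ORDER BY concept_id")$concept_id
  relationships <- data.frame(
    concept_id_1 = clinical, concept_id_2 = clinical,
    relationship_id = "Maps to", stringsAsFactors = FALSE)
  ancestors <- data.frame(
    ancestor_concept_id = clinical, descendant_concept_id = clinical,
    min_levels_of_separation = 0L, max_levels_of_separation = 0L,
    stringsAsFactors = FALSE)

  frames <- list(location = locations, care_site = care_sites,
                 provider = providers,
                 concept_relationship = relationships,
                 concept_ancestor = ancestors,
                 person = person,
                 visit_occurrence = visits,
                 condition_occurrence = conditions,
                 drug_exposure = drugs, procedure_occurrence = procedures,
                 measurement = measurements)

  # --- missingness ----------------------------------------------------------
  for (key in names(config$missingness)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    tab <- parts[1]; col <- parts[2]
    if (!tab %in% names(frames) || !col %in% names(frames[[tab]])) {
      stop("config error: unknown missingness target '", key, "'",
           call. = FALSE)
    }
    hit <- stats::runif(nrow(frames[[tab]])) < config$missingness[[key]]
    frames[[tab]][[col]][hit] <- NA
  }

  # --- check-and-repair against the planted criteria ------------------------
  truth <- brute_force_cohorts(frames, qc)
  for (q in names(member)) {
    extras <- setdiff(truth[[q]], member[[q]])
    if (length(extras) > 0) frames <- repair_cohort(frames, q, extras, qc)
  }
  truth <- brute_force_cohorts(frames, qc)
  for (q in names(member)) {
    if (!setequal(truth[[q]], member[[q]])) {
      if (is.null(config$missingness)) {
        stop("internal error: planted cohort ", q,
             " not realized by construction", call. = FALSE)
      }
      # configured missingness may legitimately drop planted members; the
      # ground truth then follows the data actually generated
      member[[q]] <- truth[[q]]
    }
  }

  for (nm in names(frames)) load_rows(con, nm, frames[[nm]])

  structure(list(cohorts = lapply(member, as.integer),
                 config = config, seed = config$seed),
            class = "ckg_ground_truth")
}

# Cohorts recomputed by scanning the generated frames: the generation-time
# oracle, independent of both the SQL and the SPARQL route.
brute_force_cohorts <- function(frames, qc = query_concepts()) {
  p <- frames$person; v <- frames$visit_occurrence
  secs <- function(x) as.numeric(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                            tz = "UTC"))
  dur_days <- (secs(v$visit_end_datetime) - secs(v$visit_start_datetime)) / 86400
  ip <- v$person_id[v$visit_concept_id %in% qc$inpatient &
                      !is.na(dur_days) & dur_days > 5]
  males <- p$person_id[p$gender_concept_id %in% qc$male]
  co <- frames$condition_occurrence
  dr <- frames$drug_exposure
  pr <- frames$procedure_occurrence
  ms <- frames$measurement
  list(
    Q1 = sort(intersect(males, unique(ip))),
    Q2 = sort(unique(co$person_id[co$condition_concept_id %in% qc$alzheimer])),
    Q3 = sort(unique(pr$person_id[pr$procedure_concept_id %in% qc$delivery])),
    Q4 = sort(unique(dr$person_id[dr$drug_concept_id %in% qc$trazodone])),
    Q5 = sort(unique(ms$person_id[ms$measurement_concept_id %in% qc$hba1c &
                                    !is.na(ms$value_as_number) &
                                    ms$value_as_number >= 10]))
  )
}

repair_cohort <- function(frames, q, extras, qc) {
  v <- frames$visit_occurrence
  switch(q,
    Q1 = {
      hit <- v$person_id %in% extras & v$visit_concept_id %in% qc$inpatient
      frames$visit_occurrence$visit_concept_id[hit] <- qc$outpatient
    },
    Q2 = {
      co <- frames$condition_occurrence
      hit <- co$person_id %in% extras & co$condition_concept_id %in% qc$alzheimer
      frames$condition_occurrence$condition_concept_id[hit] <-
        qc$background_condition
    },
    Q3 = {
      pr <- frames$procedure_occurrence
      hit <- pr$person_id %in% extras & pr$procedure_concept_id %in% qc$delivery
      frames$procedure_occurrence$procedure_concept_id[hit] <-
        qc$background_procedure
    },
    Q4 = {
      dr <- frames$drug_exposure
      hit <- dr$person_id %in% extras & dr$drug_concept_id %in% qc$trazodone
      frames$drug_exposure$drug_concept_id[hit] <- qc$background_drug
    },
    Q5 = {
      ms <- frames$measurement
      hit <- ms$person_id %in% extras & ms$measurement_concept_id %in% qc$hba1c
      frames$measurement$value_as_number[hit] <- 9.5
    })
  frames
}

#' Null out a column for selected persons
#'
#' Sets `column` to SQL NULL on every row of `table` belonging to the given
#' persons (for the `person` table, the persons' own rows).
#'
#' @param con A `DBIConnection`.
#' @param table Table name.
#' @param column Column to null; primary keys, `person_id` and
#'   `*_concept_id` key columns are treated as non-nullable.
#' @param person_ids Integer vector of person ids (empty set nulls nothing).
#' @return Number of rows changed.
#' @export
inject_nulls <- function(con, table, column, person_ids) {
  schema <- omop_schema()
  def <- schema$tables[[table]]
  if (is.null(def)) stop("unknown table '", table, "'", call. = FALSE)
  if (!column %in% names(def$columns)) {
    stop("unknown column '", column, "' in table '", table, "'", call. = FALSE)
  }
  if (identical(def$primary_key, column) || column == "person_id") {
    stop("column '", column, "' is not nullable", call. = FALSE)
  }
  if (length(person_ids) == 0) return(0L)
  sql <- paste0("UPDATE ", table, " SET ", column, " = NULL WHERE person_id",
                " IN (", paste(as.integer(person_ids), collapse = ", "), ")")
  DBI::dbExecute(con, sql)
}
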