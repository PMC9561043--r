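-- OMOP CDM v5.x table subset (SQLite dialect) plus the auxiliary
-- coding_system_map translation table.

CREATE TABLE person (
  person_id INTEGER PRIMARY KEY,
  gender_concept_id INTEGER,
  year_of_birth INTEGER,
  month_of_birth INTEGER,
  day_of_birth INTEGER,
  birth_datetime TEXT,
  race_concept_id INTEGER,
  ethnicity_concept_id INTEGER,
  location_id INTEGER,
  provider_id INTEGER,
  care_site_id INTEGER,
  person_source_value TEXT
);
CREATE TABLE visit_occurrence (
  visit_occurrence_id INTEGER PRIMARY KEY,
  person_id INTEGER,
  visit_concept_id INTEGER,
  visit_start_date TEXT,
  visit_start_datetime TEXT,
  visit_end_date TEXT,
  visit_end_datetime TEXT,
  visit_type_concept_id INTEGER,
  provider_id INTEGER,
  care_site_id INTEGER
);
CREATE TABLE condition_occurrence (
  condition_occurrence_id INTEGER PRIMARY KEY,
  person_id INTEGER,
  condition_concept_id INTEGER,
  condition_start_date TEXT,
  condition_start_datetime TEXT,
  condition_type_concept_id INTEGER,
  visit_occurrence_id INTEGER
);
CREATE TABLE drug_exposure (
  drug_exposure_id INTEGER PRIMARY KEY,
  person_id INTEGER,
  drug_concept_id INTEGER,
  drug_exposure_start_date TEXT,
  drug_exposure_start_datetime TEXT,
  drug_exposure_end_date TEXT,
  drug_exposure_end_datetime TEXT,
  drug_type_concept_id INTEGER,
  quantity NUMERIC,
  visit_occurrence_id INTEGER
);
CREATE TABLE procedure_occurrence (
  procedure_occurrence_id INTEGER PRIMARY KEY,
  person_id INTEGER,
  procedure_concept_id INTEGER,
  procedure_date TEXT,
  procedure_datetime TEXT,
  procedure_type_concept_id INTEGER,
  visit_occurrence_id INTEGER
);
CREATE TABLE measurement (
  measurement_id INTEGER PRIMARY KEY,
  person_id INTEGER,
  measurement_concept_id INTEGER,
  measurement_date TEXT,
  measurement_datetime TEXT,
  measurement_type_concept_id INTEGER,
  value_as_number NUMERIC,
  unit_concept_id INTEGER,
  unit_source_value TEXT,
  visit_occurrence_id INTEGER
);
CREATE TABLE care_site (
  care_site_id INTEGER PRIMARY KEY,
  care_site_name TEXT,
  location_id INTEGER
);
CREATE TABLE location (
  location_id INTEGER PRIMARY KEY,
  address_1 TEXT,
  city TEXT,
  state TEXT,
  zip TEXT
);
CREATE TABLE provider (
  provider_id INTEGER PRIMARY KEY,
  provider_name TEXT,
  npi TEXT,
  specialty_concept_id INTEGER,
  care_site_id INTEGER
);
CREATE TABLE concept (
  concept_id INTEGER PRIMARY KEY,
  concept_name TEXT,
  domain_id TEXT,
  vocabulary_id TEXT,
  concept_class_id TEXT,
  standard_concept TEXT,
  concept_code TEXT
);
CREATE TABLE concept_relationship (
  concept_id_1 INTEGER,
  concept_id_2 INTEGER,
  relationship_id TEXT
);
CREATE TABLE concept_ancestor (
  ancestor_concept_id INTEGER,
  descendant_concept_id INTEGER,
  min_levels_of_separation INTEGER,
  max_levels_of_separation INTEGER
);
CREATE TABLE coding_system_map (
  vocabulary_id TEXT PRIMARY KEY,
  system_uri TEXT
);
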