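---
title: "Materializing FHIR R4 RDF clinical knowledge graphs from OMOP CDM databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Materializing FHIR R4 RDF clinical knowledge graphs from OMOP CDM databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhirckg)
```

## The problem

Observational health data is most often stored relationally under the OMOP
Common Data Model (CDM): one row per person, visit, diagnosis, drug exposure,
procedure or laboratory measurement, with all clinical meaning carried by
`concept_id` foreign keys into a shared vocabulary table. FHIR, by contrast,
models the same content as typed resources (Patient, Encounter, Condition,
MedicationStatement, Observation, Procedure, ...) and has a standardized RDF
serialization in which resource elements become predicates and primitive
values hang off `fhir:value` arcs. A clinical knowledge graph in FHIR RDF
makes OMOP repositories queryable with SPARQL, linkable to ontologies, and
usable by graph-based AI methods — provided the relational-to-RDF
transformation is *faithful* (no cohort you can compute on one side is lost
or distorted on the other) and the output is *conformant* to the FHIR RDF
structure.

`fhirckg` implements that transformation end to end:

1. an embedded OMOP CDM v5.x store (SQLite through DBI) with a seedable
   miniature vocabulary;
2. a Turtle template mapping language (TML) whose entries read like the FHIR
   structures they produce;
3. a compiler from TML to flat, standard R2RML triples maps;
4. a materializer that executes triples maps against the database and emits
   the graph;
5. a declarative shape validator for the FHIR R4 structural subset;
6. a faithfulness harness running five demonstration cohort queries in both
   SQL (over OMOP) and SPARQL (over the graph) and checking set identity;
7. a synthetic OMOP generator that plants cohorts of known sizes, giving the
   harness a third, construction-time oracle.

## The mapping language and its compilation

An R2RML triples map is a SQL query plus a subject IRI template plus flat
predicate–object rules. FHIR RDF, however, is deeply nested: a Condition's
code is a CodeableConcept node holding a Coding node holding primitive
nodes. Writing that nesting in flat R2RML requires one triples map per
intermediate node and quickly becomes unreadable. TML keeps the R2RML root
constructs (`rr:logicalTable`/`rr:sqlQuery`, `rr:subjectMap`/`rr:template`,
optional `rr:class`) and leaf constructs (`rr:column`, `rr:template`,
`rr:constant`, `rr:termType`, `rr:datatype`) but lets the middle of each
entry be an ordinary nested Turtle tree whose predicates are the FHIR
element names. The mapping therefore mirrors the shape of the graph it
produces, which is also why conformance is largely guaranteed by
construction.

Compilation is a single rewrite rule, applied recursively. A nested node
reached through predicate `P` under a parent with subject template `T` and
path label `p` (the element name, e.g. `birthDate`) becomes:

* in the parent map: a predicate–object rule `(P, template T + "/" + p)`;
* a child triples map with the same SQL, subject template `T + "/" + p`, no
  class, and the node's children as its rules.

Consequently `|triples maps| = |entries| + |nested nodes|`, an exact law the
tests assert. Derived intermediate subjects are IRIs
(`.../Patient/17/birthDate`), not blank nodes: IRIs make graphs diffable,
stable under SPARQL, and trivially comparable across the compiled and the
directly interpreted routes. Duplicate sibling labels receive 0-based
ordinal segments (`.../identifier/0`) — a disambiguation, never an error.
The static case is implemented; when one SQL row set yields several rows per
derived subject (true repeating lists), the current materializer would merge
them into one node, so the shipped mapping always embeds the source table's
primary key in the subject template. Dynamic `fhir:index` ordinals are a
known limitation, documented rather than half-implemented.

Child maps reuse the parent's SQL verbatim instead of a projected subquery:
over-projection is harmless because NULL suppression (below) drops unused
cells, and provenance stays obvious.

## Materialization semantics

For each triples map and each SQL result row the materializer instantiates
the subject IRI (placeholder values percent-encoded, never failing), emits
`rdf:type` when the map declares a class, and one triple per rule — unless a
referenced column is NULL. NULL suppresses the triple; after emission, any
in-namespace IRI object that never became a subject is pruned together with
the arc pointing at it, transitively. The net effect is the intended FHIR
behavior: a person with NULL address and provider columns materializes as a
Patient with no `address` and no `generalPractitioner` arcs at all, yet
remains fully shape-conformant. Two invariants follow and are tested: every
non-NULL mapped cell contributes at least one triple, and every NULL mapped
cell contributes none.

Literal lexical forms are canonicalized per XSD datatype (integers without
decimal point, decimals with at least one fractional digit, booleans as
`true`/`false`); dates and datetimes pass through as stored. The store
writes datetimes as ISO-8601 text with seconds precision (`%Y-%m-%dT%H:%M:%S`,
UTC) and dates as ISO dates, so comparison semantics are identical in SQL
and SPARQL. Where OMOP provides dual-precision columns the mapping uses the
`*_datetime` form; day-level logic extracts the date at query time.

Three value conventions are baked into the shipped mapping's SQL, which is
deliberately the configuration surface:

* **gender**: `CASE gender_concept_id WHEN 8507 THEN 'male' WHEN 8532 THEN
  'female' ELSE 'unknown' END` — the OMOP administrative-gender convention,
  overridable through `fhir_mapping(gender_map = ...)`;
* **encounter class**: visit concepts 9201 and 262 (the two inpatient visit
  concepts in MIMIC-style OMOP instances) map to the class code `"IP"`.
  FHIR's own valueset prescribes `"IMP"`; `fhir_mapping(encounter_code =
  "IMP")` switches the emission, and the query suite accepts the same flag,
  keeping the two sides consistent. The default is `"IP"` because that is
  what OMOP ETLs actually carry;
* **coding systems**: the OMOP `vocabulary_id` is translated to the
  preferred FHIR Coding System URI through an auxiliary relational table
  (`coding_system_map`, seeded from `coding_system_table()`) joined with a
  `COALESCE` fallback to the raw id. Thirteen externally published systems
  are mappable (SNOMED, RxNorm, LOINC, UCUM, CPT4, NDFRT, NDC, CVX, the ICD
  family sharing one slot, ATC, NUCC, HGNC, ClinVar); every other
  vocabulary keeps its OMOP id, by convention. The registry publishes
  `http://snomed.info/sct`; an `https` variant exists in the wild, so
  `coding_system_table(https_snomed = TRUE)` offers it, with `http` as the
  default.

## Shape validation

The validator implements a deliberately small shape language: per-shape
lists of `(path, min, max, value-kind)` constraints with nested-shape
recursion, plus two global rules — typed resource roots must carry
`fhir:nodeRole fhir:treeRoot`, and a primitive node must have exactly one
`fhir:value` arc of the declared XSD datatype (the catch-all string rule
covers primitive-string nodes that fuller schemas leave underspecified). It
is closed-world per listed constraint but permits unlisted arcs. This is not
a full ShEx engine — no disjunction across shapes, no semantic actions — and
does not aim to be: because the mapping's structure mirrors the shape
structure, conformance is expected by construction, and the validator's job
is regression detection. It earns its keep in the tests: deleting a single
`fhir:value` arc flags exactly the affected resource root and nothing else,
and retyping one dateTime literal to string yields exactly one datatype
violation.

The shipped schema (`inst/shapes/fhir-r4-subset.yaml`) covers the eleven
resource types the mapping produces plus the datatype nodes (Identifier,
Address, HumanName, Reference, Period, Quantity, Coding, CodeableConcept,
ConceptMap groups) and six primitive shapes. Minimum cardinalities are
asserted only where the store guarantees the source column (`Resource.id`,
subject references, status codes); everything else is optional so that NULL
suppression can never produce a nonconformant graph.

## The query suite and the duration function

Five demonstration queries exercise different tables, columns and
datatypes; each exists as SQL over OMOP and as SPARQL over the graph, and
faithfulness means identical distinct-person sets:

| id | cohort | boundary |
|----|--------|----------|
| Q1 | male patients with an inpatient admission longer than 5 days | strictly `> 5`: a 5.000-day stay is excluded |
| Q2 | Alzheimer's disease diagnosis | — |
| Q3 | delivery procedure | — |
| Q4 | trazodone exposure | — |
| Q5 | HbA1c result at least 10 | inclusive `>= 10`: exactly 10.0 qualifies |

The SQL side uses OMOP "magic values" directly (`gender_concept_id = 8507`,
`visit_concept_id IN (9201, 262)`); the SPARQL side uses the graph's FHIR
vocabulary (`?gender = 'male'`, `?type = 'IP'`). Q2–Q4 select concepts by
`concept_id` from the seeded vocabulary rather than by name matching —
deterministic and independent of display strings. The one documented SQL
date idiom is SQLite's `julianday(end) - julianday(start)`.

Standard SPARQL has no datetime-difference function, so the engine registers
`ofn:daysBetween(start, end)`, defined as epoch-seconds difference divided
by 86400 (exact decimal days, negative when reversed, per-binding error on
unparseable literals — the row is dropped with a warning, matching SPARQL
expression-error semantics). Q5 additionally binds `ofn:toDate(?dt)` to
extract the date from the dateTime literal before any day-level reasoning;
distinct-person semantics make the final counts insensitive to same-day
duplicate measurements, and a dedicated test pins that case. The SPARQL
engine itself supports exactly what cohort queries need — basic graph
patterns with blank-node abbreviations, FILTER with comparisons and
boolean connectives, BIND, DISTINCT — and nothing more; it is a query
harness, not a general triple store.

## The synthetic generator

The generator emulates a critical-care-like OMOP instance at desk scale:
event dates in 2001–2012, births in 1930–2000, every person with at least
one visit, background conditions/drugs/procedures/measurements at
configurable per-person rates. Its defining feature is *planting*: the
first `n₁` persons satisfy Q1's criterion (male, one inpatient visit with
duration drawn in (5.5, 55] days), the next `n₂` satisfy Q2, and so on,
disjointly; background events use concepts disjoint from the five query
concepts, so no one else can qualify by accident. Deliberate near-misses
probe the boundaries: one background male gets an inpatient stay of exactly
5.000 days, another a stay under 5 days; two background persons get HbA1c
values in [4, 10); and the first Q5 member's value is exactly 10.0. After
generation the five cohorts are recomputed by a brute-force scan of the
in-memory frames — independent of both SQL and SPARQL — any accidental
qualifier is repaired, and the scan repeated; the returned ground truth is
therefore exact by construction. Identical (config, seed) yields
byte-identical database content.

What the generator does *not* emulate: clinically plausible value
distributions, visit overlap structure, coded-text source values, free-text
notes, or vocabulary breadth (13 concepts, not millions). Passing tests
therefore demonstrate the *transformation machinery* — NULL handling,
nesting, datatype round-trips, query equivalence — on structurally valid
data; they say nothing about mapping coverage of real-world ETL quirks.

Default study conditions used throughout the demo, tests and acceptance
script: 100 persons with planted cohorts {Q1 = 7, Q2 = 5, Q3 = 2, Q4 = 9,
Q5 = 4} at seed 42, which materializes to roughly 16–17 thousand triples and
runs the full pipeline in a few seconds; the property suite repeats the
three-way identity check across 20 further seeds at 50 persons. These sizes
were chosen so the whole evidence chain re-runs comfortably on a laptop
while every code path (all five queries, NULL suppression, boundary rows)
is exercised.

## Numerical and degenerate-input choices

* Decimal canonical form keeps at least one fractional digit (`10.0`), so a
  whole-valued measurement still reads as a decimal; numeric comparison in
  SPARQL parses lexical forms, so `10.0 >= 10` holds either way.
* Percent-encoding applies to every template placeholder value; an IRI is
  never a reason for failure.
* An empty database materializes an empty graph; an empty shape schema
  validates vacuously (`checked = 0`, conformance reported as `NA`); empty
  cohorts compare as identical empty sets.
* `julianday` arithmetic and `ofn:daysBetween` agree because both reduce to
  seconds-scale subtraction on the same ISO lexical forms; Q1's strict
  inequality is evaluated on exact day fractions on both sides.
* The schema ships all twelve OMOP tables of the subset, including
  `care_site`; the default mapping draws on eleven of them, leaving
  `care_site` unmapped alongside the redundant date-part columns (both
  kept so the store mirrors the CDM shape it claims).

## Known limitations

* TML supports one logical table per entry; cross-table R2RML joins
  (`rr:RefObjectMap`), named graphs and `rr:inverseExpression` are out of
  scope. Joins belong in the entry's SQL.
* The graph is always materialized; there is no query-time virtualization
  or SPARQL endpoint hosting.
* Repeating elements per subject require ordinal-bearing subject templates
  (see above).
* The shape language is a structural subset, not full ShEx; validation
  against official unmodified schemas is a compatible external check, not a
  package dependency.
* The shipped vocabulary is a seed, not a terminology service; real
  deployments would point the store at an OHDSI vocabulary load.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(out_dir = "ckg-run", n_persons = 100,
                                    seed = 42))
res$status                                  # 0
res$faithfulness$per_query                  # 5/5 identical, {7,5,2,9,4}
res$shape_report$overall_conformance        # 1
mapping_audit(fhir_mapping())$element_mappings  # 104
```

The same chain is reproducible from a shell via `inst/cli/fhirckg demo` and
is what `scripts/acceptance.R` recomputes and reports as JSON.
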