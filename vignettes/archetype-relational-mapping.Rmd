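---
title: "Archetype relational mapping: model, mapping rules, and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetype relational mapping: model, mapping rules, and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armpersist)
```

## The problem

Two-level clinical information modelling separates a small, stable reference
model from volatile domain content expressed as *archetypes* — constraint
models that each describe one clinical concept (a lab test, an imaging exam,
a person) as a tree of typed data items, collection structures and slots
where other archetypes plug in. The open question for production systems is
persistence: the generic answer, a Node+Path (entity–attribute–value) table
of `<node path, serialized value>` rows, is maximally flexible but pays for
it with full-table scans and massive path redundancy.

`armpersist` implements the alternative: archetype relational mapping (ARM).
Templates attach persistence constraints to each archetype — an
*identification data item* (IDI) that uniquely identifies instances, *query
data items* (QDIs) that are frequent search conditions, and mappings between
specialized and generalized archetypes — and a fixed rule set turns
archetypes plus templates into a conventional relational schema. The package
also ships the Node+Path backend as the comparison baseline, a synthetic
workload generator, and a benchmark harness, so the two designs can be
compared end to end on equal data.

## Mapping rules

`map_schema()` applies, per archetype:

1. **Archetype → table.** By default only "root" archetypes — those not used
   exclusively as specialization parents or single-occurrence slot targets —
   get standalone tables (`standalone_all = TRUE` widens this). That is how
   the worked fixture suite lays out: 17 archetypes become 12 tables.
2. **Basic items.** Single-occurrence items become columns, one per resolved
   field of the basic type (a `DvQuantity` yields `_magnitude` FLOAT and
   `_units` NVARCHAR; reference fields such as `DvCodedText.definingCode`
   expand through the type registry). Multiple-occurrence items become a
   standalone table with a foreign key back to the archetype's key.
3. **Identification.** The IDI column carries the unique clustered index.
   Without an IDI a generated `id` column (invisible to archetype paths) is
   added and clustered.
4. **Query items** get non-clustered single-column indexes.
5. **Slots.** A single-occurrence slot embeds the target archetype's items
   inline (recursively, with cycle detection); a multiple-occurrence slot
   becomes a foreign-key column in the *target* archetype's table.
6. **Collections.** Single-occurrence collections are flattened; repeating
   collections become child tables with a foreign key and an `ordinal`
   column (an implementation addition so retrieval preserves repetition
   order).
7. **Propagation.** The parent's query items are copied into each repeating
   child table as indexed columns, so the frequent conditions of ancestors
   can be answered without climbing the hierarchy. Individual propagations
   can be suppressed in the template (`suppressed_propagations`); the
   default is propagate-all.
8. **Naming.** Tables: reference-model class letter (`OBSERVATION → O`,
   `INSTRUCTION → I`, demographic `PERSON → D`, `CLUSTER → C`) plus the
   CamelCase concept name, version stripped; child tables append the
   CamelCase collection path. Columns join the item names along the path
   with `_` plus the field suffix. Two details are worth calling out because
   they are needed to reproduce the published column names: collection
   segments are *omitted* from column names (while slot segments are kept),
   and a trailing repetition of the item name collapses — an item `id` of
   type `DvIdentifier` (field `id`) yields column `id`, and a patient
   identifier reached through a slot yields
   `patientIdentifier_identifier_id`. Over-long names truncate and append a
   4-hex-digit digest of the full name, deterministically.

Provenance is kept bidirectionally: every data column maps to exactly one
`(archetype, node path, field)` and back, which is what query translation
and instance retrieval run on.

```{r schema}
suite <- build_fixture_suite()
schema <- map_fixture_schema(suite)
names(schema$tables)
```

## Versions of an archetype

`classify_relationship()` follows the compatibility semantics of archetype
change: a **revision** (descriptions changed, attributes or value ranges
expanded, optional items added) keeps old data valid, so both versions share
one table and new-only columns are added nullable. A **specialization**
(concept name extended, constraints equal or stronger) always maps to its
own table. Everything else is a **new version** — including making a
mandatory item optional, which loosens a constraint yet is still
incompatible under the published change taxonomy, because consumers of the
old contract may rely on the item's presence. New versions either get a
table per version (the version suffix stays in the name) or are merged:
`merge_versions(..., strategy = "MERGE_AND_CONVERT")` emits a migration plan
(create, copy with per-column transforms, verify row counts, drop) that
`apply_migration()` executes with checksum verification. Only identity,
rename and text/number casts are supported as transforms; archetype-supplied
conversion algorithms have no specified form and are out of scope.

## The embedded engine and DDL

The stores run on a small in-package relational engine (typed columns,
unique and composite-unique indexes, foreign-key existence checks) backed by
`data.table`. It exists so that storing, querying and measuring need no
external database service. DDL is still first-class: `emit_ddl()` renders
the schema deterministically for two dialects — `sqlite`, where the
clustered index is emulated by making the key the `PRIMARY KEY` (recorded in
an SQL comment), and `generic-ansi`, which keeps NVARCHAR types and emits
`CLUSTERED` as a comment. The sqlite output is executed on a real SQLite
database (through the Python standard library, `inst/tools/
sqlite_introspect.py`) and the introspected catalog is compared against the
model — the execute-and-introspect oracle used by the test suite.

## Query semantics

A query is a conjunction of `(path, field, comparator, literal)` conditions
with comparators `=`, `>=`, `<=`, `LIKE` — the forms the benchmark needs. On
a repeating group, a condition holds if *some* repetition satisfies it;
conditions that must hold in the *same* repetition share a group tag (this
is what translated name/value pairs use, so "white cell count ≥ 4" means one
repetition holding both the name and the value). Clauses over different
archetypes intersect at subject level, matching "find all patients with …
and …". Execution is stepwise — one simple scan per condition or bundle,
key sets intersected in the client — mirroring how the mapped database is
meant to be queried (simple clauses, no nested joins); numeric literals
compare numerically even against text-stored values, text comparisons are
byte-wise, and datetimes rely on the ISO-8601 rendering being
lexicographically sortable.

Specialized↔generalized translation uses the EAV mapping files: each
specialized condition becomes a same-repetition (name = display-name, field
cmp value) pair on the generalized group, and the reverse direction
re-binds name/value pairs onto the specialized column and unions over the
mappings that cover all named analytes.

## The Node+Path baseline

One table per concept holds `<instance key, ordinal, node path, serialized
value>`; the full path is stored per row on purpose — that redundancy is the
phenomenon under study, so it is reproduced, not optimized away. Values use
a typed-prefix text encoding (`t:`/`i:`/`f:`, floats at 17 significant
digits so doubles round-trip exactly); no printed serialization format
exists for this backend, so the encoding is an implementation decision.
Repetition ordinals are zero-based per group; nested groups fold the parent
ordinal in (`parent × 10^5 + index`) to keep `(key, ordinal, path)` unique.
An instance with no populated leaves still writes one registration row so it
remains addressable. Queries are path-predicate scans with per-instance
grouping — the backend deliberately has no per-field indexes.

## Synthetic workload

`generate_dataset()` emulates the integrated-viewer workload shape: patients
assigned to clinicians, imaging requests/exams with image series, lab
requests and lab tests split between five specialized panels and the
generalized form. Per-entity counts draw from log-normal distributions
truncated to `[min, max]` with the mean matched to the configured average —
log-normal because the published min/average/max triples (1/7/50 patients
per clinician, 1/3/26 exams per patient, 1/363/10664 images per exam,
1/23/425 lab tests per patient, 1/168/4477 results per test) imply a heavy
right tail. The large distributions scale by a factor (default 0.05) applied
to mean and max, with a floor of 2 on the scaled mean so desk-scale
distributions stay non-degenerate. Analyte values are normal around clinical
reference midpoints (for example PaO2 at 150 ± 60 mmHg, sodium at
140 ± 3 mmol/L) with both tails crossing the benchmark thresholds, so
threshold searches select proper nonempty subsets. All randomness hangs off
one seed; the same parameters reproduce the instance stream byte for byte.

What the generator does *not* emulate: clinically realistic correlations
between analytes or over time, missingness structure, free-text content, or
hospital-scale volumes. Passing tests therefore show correctness and
ordinal performance structure on workload-shaped data, not absolute
performance on real records.

## Benchmark design and what is asserted

`build_queries()` encodes the seven tests (ids 1.1–7.2, twenty queries):
five data-retrieving tests bound to the entities at the minimum /
nearest-average / maximum of the relevant count distribution in the loaded
dataset, and two patient-searching tests with fixed thresholds (blood gases
with 1/3/5 conditions; cross-panel with 3/5 conditions). Binding the
min/avg/max variants to distribution extremes of the synthetic dataset is an
implementation decision — the published variants bind to specific hospital
entities that do not exist here.

`run_benchmark()` first asserts result-set equality across backends for
every query (correctness precedes performance), then times each query:
each repetition re-executes the query from scratch over fresh result
structures with a garbage-collection pass before the timer — the in-process
analogue of disabling the database cache — and the mean over repetitions is
reported (10 repetitions by default, each timed over 3 inner executions to
stay above timer resolution).

Timing assertions are ordinal only; milliseconds are hardware-bound and
never compared to published figures. Asserted at the default desk scale:
the Node+Path footprint (serialized CSV bytes per backend) exceeds ARM's;
Node+Path is not faster than ARM on any test-6/7 query; and within each of
tests 1–5 the measured time rises from the min-count entity through the
average to the max. The last property is asserted for tests 1–5 only
because only those have min/avg/max *scenario* variants; the variants of
tests 6–7 change the number of conditions instead, which moves two costs in
opposite directions (more scans, but fewer matches to materialize), so no
direction is asserted there.

## Numerical and degenerate-input choices

* Nullability follows occurrence: lower bound 0 → nullable, 1 → NOT NULL.
* `DvDateTime` stays NVARCHAR with an ISO-8601 rendering so range queries
  behave lexicographically.
* `DvProportion` maps only its declared `precision` field; numerator and
  denominator FLOAT columns exist behind
  `schema_config(dv_proportion_extended = TRUE)`, default off, because the
  published type table does not map them.
* A repetition record carrying no values is canonicalized away (it is
  indistinguishable from absence), while an *empty repetition list* is data
  and round-trips as an empty list.
* Empty archetypes, duplicate paths, slot cycles, occurrence violations and
  duplicate identification values are errors, not warnings; template
  validation returns violations as data.
* Result sets order keys numerically when all keys parse as numbers,
  byte-wise otherwise, making digests deterministic.
* Queries against an archetype that is both standalone and embedded answer
  from the standalone table only; the embedded occurrences are recorded in
  the schema's secondary provenance for callers that want to widen.

## Problem sizes

The shipped tests run the whole pipeline at desk scale: 200 patients at
scale 0.05 (about 2,300 instances) for the cross-backend/oracle and
benchmark checks, 1,000 randomized instances for the round-trip property,
10 seeds for the generator calibration check, and 10 timed repetitions per
benchmark cell. These sizes are the package's test conditions; the mapping
and store code paths do not depend on them.

## Known limitations

Full ADL parsing, terminology binding, AQL, transactions and concurrency
control are out of scope; the archetype dialect captures exactly the
semantics the mapper consumes. Index design stops at the IDI/QDI rules —
there are no adaptive or composite indexes. The embedded engine is a test
vehicle, not a database: it enforces the constraints the mapper emits and
nothing more.
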