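# armpersist

Relational persistence for archetype-based electronic health records.

Two-level clinical modelling keeps a small stable reference model and
expresses volatile domain content as **archetypes** — constraint models of
single clinical concepts (a lab test, an imaging exam, a person) built from
typed data items, collection structures and slots. Persisting archetype
instances is the hard part: the generic Node+Path answer stores every leaf
as an entity–attribute–value row `<node path, serialized value>` and pays
with full-table scans and path redundancy.

`armpersist` implements **archetype relational mapping (ARM)**: templates
attach persistence constraints to each archetype — one *identification data
item* (IDI, the unique clustered key), *query data items* (QDIs,
non-clustered indexes that also propagate into child tables), and
specialized↔generalized mappings — and a fixed rule set maps archetypes to
a conventional relational schema:

* archetype → table; single-occurrence items → typed columns (one per
  resolved field of the basic data type); repeating items and collections →
  child tables with foreign keys and an ordinal;
* single-occurrence slots embed the target archetype inline, repeating
  slots become foreign keys in the target's table;
* IDI → unique clustered index (or a generated, archetype-invisible `id`);
  QDIs → non-clustered indexes, copied into repeating child tables so
  ancestor conditions need no joins;
* deterministic naming (class letter + CamelCase concept; columns join item
  names and field suffix; digest-based shortening).

The package is the whole experiment, not just the mapper: it ships an
embedded relational engine backing an ARM store *and* a Node+Path store, a
DDL emitter validated by executing on SQLite and introspecting the result,
archetype-version handling (shared tables for revisions, migration plans
for incompatible versions), query translation between specialized and
generalized lab archetypes, a seeded synthetic generator shaped like an
integrated-viewer hospital workload, and a 20-query benchmark harness that
asserts cross-backend result equality before reporting any timing.

For whom: health-informatics engineers evaluating openEHR-style persistence
designs, and anyone who wants a reproducible, desk-scale testbed comparing
schema-mapped storage against an EAV baseline on identical data.

## Worked example

```r
library(armpersist)

suite  <- build_fixture_suite()          # 17 archetypes, 5 templates, 5 EAV mappings
schema <- map_fixture_schema(suite)
length(schema$tables)
#> [1] 12
names(schema$tables)[1:4]
#> [1] "DPersonPatient" "IRequestImagingExam" "OImagingExam"
#> [4] "OImagingExamImageDetails"

ds    <- generate_dataset(dataset_params(seed = 42, n_patients = 50))
length(ds$instances)
#> [1] 544
store <- arm_store(schema, suite$archetypes)
load_instances(store, ds$instances)

# patients with PaO2 >= 129 mmHg and PaCO2 >= 27 mmHg in blood gas tests
q <- query_spec(query_clause("openEHR-EHR-OBSERVATION.lab_test-blood_gases.v1",
                             list(condition("[Structure]/[PaO2]",  ">=", 129),
                                  condition("[Structure]/[PaCO2]", ">=", 27))),
                grouping = "subject")
res <- run_query(store, q)
res$keys
#> [1] "P000003" "P000009" "P000021" "P000025" "P000040" "P000041"

# the EAV baseline answers identically on the same data
np <- np_store(schema, suite$archetypes)
load_instances(np, ds$instances)
result_equal(res, np_run_query(np, q))
#> [1] TRUE
round(db_size_bytes(np) / db_size_bytes(store), 2)   # EAV storage overhead
#> [1] 2.74
```

The six keys are patient identifiers: the query groups at subject level, so
each key is a distinct patient having at least one blood-gas test meeting
both thresholds. The last two lines are the package's two headline claims
in miniature — the schema-mapped store and the Node+Path store are
query-equivalent, and the Node+Path representation needs severalfold more
storage for the same instances.

A thin command-line wrapper over the same functions lives at
`inst/cli/arm-tool.R` (`synth`, `load`, `query`, `bench` subcommands).

## Package layout

| Area | Files |
|---|---|
| Basic type registry, archetypes, versions | `R/types-registry.R`, `R/archetype.R` |
| Templates, ARM constraints, EAV mappings | `R/template.R`, `R/eav-mapping.R` |
| Mapping rules, naming, version merging | `R/schema-mapper.R`, `R/names.R` |
| DDL, dialects, migrations | `R/ddl.R` |
| Embedded engine, ARM store, Node+Path store | `R/engine.R`, `R/store-arm.R`, `R/store-nodepath.R` |
| Queries, translation, oracle | `R/query.R`, `R/translate.R`, `R/oracle.R` |
| Fixtures, synthetic data, benchmark | `R/fixtures.R`, `R/synth.R`, `R/bench.R` |

The methods vignette
(`vignettes/archetype-relational-mapping.Rmd`) documents the mapping rules,
query semantics, generator distributions, benchmark design and the
reasoning behind the open design choices.
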