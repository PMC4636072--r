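# Shared fixtures, memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

fix_suite <- function() {
  if (is.null(.fixture_cache$suite))
    .fixture_cache$suite <- build_fixture_suite()
  .fixture_cache$suite
}

fix_schema <- function() {
  if (is.null(.fixture_cache$schema))
    .fixture_cache$schema <- map_fixture_schema(fix_suite())
  .fixture_cache$schema
}

# a tiny standalone archetype pair for engine/version tests
tiny_vitals_v1 <- function() {
  archetype("openEHR-EHR-OBSERVATION.vitals.v1", list(
    basic_item("patient", "DvText", "1..1"),
    basic_item("heartRate", "DvCount", "0..1")))
}

tiny_suite <- function(...) {
  archs <- list(...)
  stats::setNames(archs, vapply(archs, `[[`, "", "id"))
}

canon_of <- function(inst, suite) {
  validate_instance(inst, suite[[inst$archetype_id]], suite)
}

json_equal <- function(a, b) identical(canonical_json(a), canonical_json(b))

# small deterministic dataset shared by store/query/bench tests
small_dataset <- function(seed = 7, n = 25) {
  key <- paste0("ds", seed, "_", n)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_dataset(dataset_params(seed = seed,
                                                             n_patients = n))
  .fixture_cache[[key]]
}

loaded_backends <- function(seed = 7, n = 25) {
  key <- paste0("bk", seed, "_", n)
  if (is.null(.fixture_cache[[key]])) {
    suite <- fix_suite(); sch <- fix_schema()
    ds <- small_dataset(seed, n)
    st <- arm_store(sch, suite$archetypes)
    np <- np_store(sch, suite$archetypes)
    load_instances(st, ds$instances)
    load_instances(np, ds$instances)
    .fixture_cache[[key]] <- list(arm = st, np = np, ds = ds)
  }
  .fixture_cache[[key]]
}
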