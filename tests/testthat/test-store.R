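test_that("store and retrieve are inverse over randomized instances", {
  suite <- fix_suite(); sch <- fix_schema()
  set.seed(31)
  st <- arm_store(sch, suite$archetypes)
  cnt <- new.env()
  roots <- names(sch$plans)
  for (i in 1:120) {
    a <- suite$archetypes[[sample(roots, 1)]]
    inst <- random_instance(a, suite$archetypes, cnt)
    key <- store_instance(st, inst)
    back <- retrieve_instance(st, a$id, key)
    expect_true(json_equal(back$data, canon_of(inst, suite$archetypes)$data),
                info = paste(a$id, key))
  }
})

test_that("a lab instance with repeated results lands as one parent row plus child rows", {
  suite <- fix_suite(); sch <- fix_schema()
  st <- arm_store(sch, suite$archetypes)
  reps <- lapply(1:3, function(i) list(`Test item` = list(value = "Sodium"),
                                       Result = list(value = as.character(140 + i)),
                                       `Result unit` = list(value = "mmol/L")))
  inst <- archetype_instance("openEHR-EHR-OBSERVATION.lab_test-general.v1", list(
    id = list(id = "LT1"), receiverOrderIdentifier = list(value = "RQ1"),
    patient = list(value = "P1"),
    Structure = list(Result = reps)))
  key <- store_instance(st, inst)
  expect_identical(key, "LT1")
  main <- db_table(st, "OLabTestGeneral")
  child <- db_table(st, "OLabTestGeneralStructureResult")
  expect_identical(nrow(main), 1L)
  expect_identical(nrow(child), 3L)
  expect_identical(child$OLabTestGeneral_id, rep("LT1", 3))
  expect_identical(child$ordinal, 0:2)
  # propagated query-item values equal the parent row's values
  expect_identical(child$OLabTestGeneral_patient_value, rep("P1", 3))
  expect_identical(child$OLabTestGeneral_receiverOrderIdentifier_value,
                   rep("RQ1", 3))

  # duplicate identification value violates the unique clustered key
  expect_error(store_instance(st, inst), class = "unique_violation")
})

test_that("occurrence and mandatory-leaf violations are rejected", {
  suite <- fix_suite(); sch <- fix_schema()
  st <- arm_store(sch, suite$archetypes)
  # two values for a single-occurrence item
  bad <- archetype_instance("openEHR-EHR-OBSERVATION.lab_test-general.v1", list(
    id = list(id = "LT2"), patient = list(list(value = "P1"), list(value = "P2")),
    Structure = list(`Test name` = list(value = "x"))))
  expect_error(store_instance(st, bad), class = "occurrence_violation")
  # missing mandatory subject
  bad2 <- archetype_instance("openEHR-EHR-OBSERVATION.lab_test-general.v1", list(
    id = list(id = "LT3"), Structure = list(`Test name` = list(value = "x"))))
  expect_error(store_instance(st, bad2), class = "missing_mandatory")
  # unknown node name
  bad3 <- archetype_instance("openEHR-EHR-OBSERVATION.lab_test-general.v1", list(
    id = list(id = "LT4"), patient = list(value = "P1"),
    Structure = list(bogus = list(value = "x"))))
  expect_error(store_instance(st, bad3), class = "bad_tree")
})

test_that("empty repetition lists round-trip as empty lists, not absent nodes", {
  suite <- fix_suite(); sch <- fix_schema()
  st <- arm_store(sch, suite$archetypes)
  inst <- archetype_instance("openEHR-EHR-OBSERVATION.imaging_exam.v1", list(
    id = list(id = "EX9"), patient = list(value = "P9"),
    `Image details` = list()))
  key <- store_instance(st, inst)
  back <- retrieve_instance(st, "openEHR-EHR-OBSERVATION.imaging_exam.v1", key)
  expect_true(!is.null(back$data$`Image details`))
  expect_length(back$data$`Image details`, 0)
})

test_that("retrieval of an unknown key reports not-found", {
  suite <- fix_suite(); sch <- fix_schema()
  st <- arm_store(sch, suite$archetypes)
  expect_error(retrieve_instance(st, "openEHR-EHR-OBSERVATION.imaging_exam.v1",
                                 "nope"),
               class = "not_found")
})

test_that("query semantics follow the brute-force contract", {
  b <- loaded_backends()
  suite <- fix_suite(); sch <- fix_schema()
  ds <- b$ds
  prep <- oracle_prepare(ds$instances, sch, suite$archetypes)
  gid <- "openEHR-EHR-OBSERVATION.lab_test-general.v1"

  # vacuous conjunction selects every instance of the archetype
  all_spec <- query_spec(query_clause(gid))
  r <- run_query(b$arm, all_spec)
  n_gen <- sum(vapply(ds$instances, function(i)
    identical(i$archetype_id, gid), TRUE))
  expect_length(r$keys, n_gen)
  expect_true(result_equal(r, oracle_query(prep, all_spec)))

  # LIKE over subject ids
  like_spec <- query_spec(query_clause(
    "openEHR-EHR-INSTRUCTION.request-lab_test.v1",
    list(condition("[patient]", "LIKE", "P00000_"))))
  expect_true(result_equal(run_query(b$arm, like_spec),
                           oracle_query(prep, like_spec)))

  # same-repetition bundle vs independent conditions on a repeating group
  st <- arm_store(sch, suite$archetypes)
  reps <- list(
    list(`Test item` = list(value = "Sodium"), Result = list(value = "120")),
    list(`Test item` = list(value = "Potassium"), Result = list(value = "200")))
  inst <- archetype_instance(gid, list(
    id = list(id = "LTX"), patient = list(value = "PX"),
    Structure = list(Result = reps)))
  store_instance(st, inst)
  same_rep <- query_spec(query_clause(gid, list(
    condition("[Structure]/[Result]/[Test item]", "=", "Sodium", group = "g"),
    condition("[Structure]/[Result]/[Result]", ">=", 150, group = "g"))))
  indep <- query_spec(query_clause(gid, list(
    condition("[Structure]/[Result]/[Test item]", "=", "Sodium"),
    condition("[Structure]/[Result]/[Result]", ">=", 150))))
  expect_length(run_query(st, same_rep)$keys, 0)   # 150+ sits on Potassium
  expect_identical(run_query(st, indep)$keys, "LTX")
  orc <- oracle_query(list(inst), same_rep, sch, suite$archetypes)
  expect_length(orc$keys, 0)
  expect_identical(oracle_query(list(inst), indep, sch,
                                suite$archetypes)$keys, "LTX")
})
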