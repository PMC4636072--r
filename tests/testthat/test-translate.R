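test_that("a specialized condition becomes a same-repetition name/value pair", {
  suite <- fix_suite()
  fbc <- "openEHR-EHR-OBSERVATION.lab_test-full_blood_count.v1"
  m <- suite$eav_maps[[fbc]]
  spec <- query_spec(query_clause(fbc, list(
    condition("[Structure]/[White cell count]", ">=", 4))),
    grouping = "subject")
  tq <- translate_specialized_query(spec, m, suite$archetypes)
  cl <- tq$clauses[[1]]
  expect_identical(cl$archetype_id, "openEHR-EHR-OBSERVATION.lab_test-general.v1")
  expect_length(cl$conditions, 2)
  name_c <- cl$conditions[[1]]; val_c <- cl$conditions[[2]]
  expect_identical(name_c$path, "[Structure]/[Result]/[Test item]")
  expect_identical(name_c$op, "=")
  expect_identical(name_c$value, "White cell count")
  expect_identical(val_c$path, "[Structure]/[Result]/[Result]")
  expect_identical(val_c$op, ">=")
  expect_identical(val_c$value, 4)
  expect_identical(name_c$group, val_c$group)  # same repetition

  # empty condition set stays empty
  tq0 <- translate_specialized_query(query_spec(query_clause(fbc),
                                                grouping = "subject"),
                                     m, suite$archetypes)
  expect_length(tq0$clauses[[1]]$conditions, 0)

  # a path outside the mapping is untranslatable
  expect_error(translate_specialized_query(
    query_spec(query_clause(fbc, list(condition("[patient]", "=", "x"))),
               grouping = "subject"),
    m, suite$archetypes),
    class = "untranslatable")
})

test_that("generalized and specialized storage answer queries identically", {
  suite <- fix_suite(); sch <- fix_schema()
  bg_id <- "openEHR-EHR-OBSERVATION.lab_test-blood_gases.v1"
  m <- suite$eav_maps[[bg_id]]
  ds <- small_dataset(13, 30)
  bg <- Filter(function(i) identical(i$archetype_id, bg_id), ds$instances)
  expect_gt(length(bg), 3)

  st_spec <- arm_store(sch, suite$archetypes)
  for (i in bg) store_instance(st_spec, i)
  st_gen <- arm_store(sch, suite$archetypes)
  for (i in bg) store_instance(st_gen,
                               specialized_to_generalized(i, m, suite$archetypes))

  spec_q <- query_spec(query_clause(bg_id, list(
    condition("[Structure]/[PaO2]", ">=", 129),
    condition("[Structure]/[PaCO2]", ">=", 27))),
    grouping = "subject")
  direct <- run_query(st_spec, spec_q)
  translated <- run_query(st_gen, translate_specialized_query(spec_q, m,
                                                              suite$archetypes))
  expect_gt(length(direct$keys), 0)
  expect_lt(length(direct$keys), length(bg))
  expect_identical(direct$keys, translated$keys)

  # and the reverse direction: a generalized-native query against the
  # specialized tables
  gen_q <- translate_specialized_query(spec_q, m, suite$archetypes)
  back <- translate_generalized_query(gen_q, suite$eav_maps, suite$archetypes)
  expect_length(back, 1)   # only the blood-gas mapping covers these analytes
  expect_identical(run_query(st_spec, back[[1]])$keys, translated$keys)
})
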