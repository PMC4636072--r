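test_that("DDL emission is deterministic and type-faithful", {
  sch <- fix_schema()
  d1 <- emit_ddl(sch)
  d2 <- emit_ddl(sch)
  expect_identical(d1, d2)
  # quantity-backed columns render as REAL + TEXT on sqlite,
  # FLOAT + NVARCHAR on generic ANSI
  expect_match(d1, "PaO2_magnitude REAL")
  expect_match(d1, "PaO2_units TEXT")
  ansi <- emit_ddl(sch, arm_dialect("generic-ansi"))
  expect_match(ansi, "PaO2_magnitude FLOAT")
  expect_match(ansi, "PaO2_units NVARCHAR\\(255\\)")
  expect_match(ansi, "-- CLUSTERED")
  # sqlite dialect records the clustered emulation
  expect_match(d1, "emulated via PRIMARY KEY")
})

test_that("an empty schema emits empty DDL", {
  empty <- map_schema(list())
  expect_identical(emit_ddl(empty), "")
})

test_that("executing the DDL on sqlite reproduces the schema model", {
  sch <- fix_schema()
  got <- introspect_sqlite(emit_ddl(sch))
  want <- expected_sqlite_introspection(sch)
  norm <- function(x) lapply(x, function(t) {
    t$indexes <- as.list(sort(unlist(t$indexes) %||% character())); t
  })
  expect_identical(canonical_json(norm(got)), canonical_json(norm(want)))
})

test_that("migration copies rows with count and per-column checksum preserved", {
  o <- tiny_vitals_v1()
  n <- archetype("openEHR-EHR-OBSERVATION.vitals.v2",
                 list(basic_item("patient", "DvText", "1..1"),
                      basic_item("heartRate", "DvQuantity", "0..1")))
  sch <- merge_versions(map_schema(tiny_suite(o)), o, n,
                        strategy = "MERGE_AND_CONVERT",
                        conversions = list(heartRate_magnitude =
                                             list(source = "heartRate_magnitude",
                                                  transform = "cast_number")),
                        suite = tiny_suite(o, n))
  expect_length(sch$migration_plans, 1)
  db <- arm_db(); deploy_schema(db, sch)
  set.seed(99)
  nrows <- 40L
  db_insert(db, "OVitals", list(id = seq_len(nrows),
                                patient_value = sprintf("P%03d", seq_len(nrows)),
                                heartRate_magnitude = sample.int(150L, nrows,
                                                                 replace = TRUE)))
  before <- db_table(db, "OVitals")
  rep <- apply_migration(db, sch$migration_plans[[1]])
  expect_true(all(rep$ok))
  expect_true(all(attr(rep, "checksums")))
  after <- db_table(db, "OVitalsV2")
  expect_identical(nrow(after), nrows)
  expect_identical(sort(after$patient_value), sort(before$patient_value))
  expect_equal(sort(after$heartRate_magnitude),
               sort(as.numeric(before$heartRate_magnitude)))
  expect_false("OVitals" %in% db_table_names(db))

  # empty source migrates to an empty target
  db2 <- arm_db(); deploy_schema(db2, sch)
  rep2 <- apply_migration(db2, sch$migration_plans[[1]])
  expect_true(all(rep2$ok))
  expect_identical(nrow(db_table(db2, "OVitalsV2")), 0L)

  # a plan missing a mapping for a not-null column aborts before copying
  plan <- sch$migration_plans[[1]]
  plan$mapping <- Filter(function(m) m$target != "patient_value", plan$mapping)
  db3 <- arm_db(); deploy_schema(db3, sch)
  db_insert(db3, "OVitals", list(id = 1L, patient_value = "P1",
                                 heartRate_magnitude = 60L))
  expect_error(apply_migration(db3, plan), class = "missing_conversion")
  expect_identical(nrow(db_table(db3, "OVitals")), 1L)  # source untouched
})
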