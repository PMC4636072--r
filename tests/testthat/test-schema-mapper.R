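test_that("the fixture suite maps to the published worked schema", {
  sch <- fix_schema()
  expect_setequal(names(sch$tables),
                  c("DPersonPatient", "IRequestImagingExam", "OImagingExam",
                    "OImagingExamImageDetails", "IRequestLabTest",
                    "OLabTestGeneral", "OLabTestGeneralStructureResult",
                    "OLabTestBloodGases", "OLabTestFullBloodCount",
                    "OLabTestLiverFunction", "OLabTestThyroid",
                    "OLabTestUreaAndElectrolytes"))
  # the patient table is keyed (clustered, unique) on the patient identifier
  pp <- sch$tables$DPersonPatient
  expect_identical(pp$key_col, "patientIdentifier_identifier_id")
  ci <- Filter(function(i) i$clustered, pp$indexes)
  expect_length(ci, 1)
  expect_true(ci[[1]]$unique)
  expect_identical(ci[[1]]$columns, "patientIdentifier_identifier_id")
  # the result child table carries the propagated, non-clustered-indexed
  # patient column
  cr <- sch$tables$OLabTestGeneralStructureResult
  pq <- Filter(function(c) identical(c$role, "PROPAGATED_QUERY"), cr$columns)
  expect_true("OLabTestGeneral_patient_value" %in%
                vapply(pq, `[[`, "", "name"))
  nci <- unlist(lapply(Filter(function(i) !i$clustered, cr$indexes),
                       `[[`, "columns"))
  expect_true("OLabTestGeneral_patient_value" %in% nci)
  expect_identical(cr$foreign_keys[[1]]$target_table, "OLabTestGeneral")
  expect_identical(cr$foreign_keys[[1]]$target_column, "id")
})

test_that("the mapped schema equals the frozen golden model", {
  got <- schema_structure(fix_schema())
  want <- schema_structure(golden_schema())
  expect_identical(canonical_json(got), canonical_json(want))
})

test_that("every table has exactly one clustered unique index on its key", {
  for (t in fix_schema()$tables) {
    ci <- Filter(function(i) isTRUE(i$clustered), t$indexes)
    expect_length(ci, 1)
    expect_true(ci[[1]]$unique, info = t$name)
    expect_identical(ci[[1]]$columns, t$key_col, info = t$name)
  }
})

test_that("provenance is a bijection over data columns", {
  sch <- fix_schema()
  prov <- sch$provenance
  key <- paste(prov$archetype_id, prov$node_path, prov$suffix)
  expect_identical(anyDuplicated(key), 0L)
  colkey <- paste(prov$table, prov$column)
  expect_identical(anyDuplicated(colkey), 0L)
  # every DATA column appears in the map and vice versa
  data_cols <- unlist(lapply(sch$tables, function(t)
    lapply(Filter(function(c) identical(c$role, "DATA"), t$columns),
           function(c) paste(t$name, c$name))), use.names = FALSE)
  expect_setequal(colkey, data_cols)
})

test_that("archetypes without identification items get a generated clustered key", {
  a <- archetype("openEHR-EHR-OBSERVATION.note.v1",
                 list(basic_item("item", "DvText", "0..1")))
  sch <- map_schema(tiny_suite(a))
  t <- sch$tables$ONote
  expect_identical(vapply(t$columns, `[[`, "", "name"), c("id", "item_value"))
  expect_identical(t$key_col, "id")
  expect_identical(t$columns[[1]]$role, "GENERATED_ID")
  expect_identical(t$columns[[1]]$provenance, "generated")
  expect_identical(vapply(t$columns, `[[`, "", "storage_kind"),
                   c("INTEGER", "NVARCHAR"))
})

test_that("single-occurrence slots embed; MANY slots become foreign keys", {
  sch <- fix_schema()
  # embedded person_name appears inline in the patient table
  cols <- vapply(sch$tables$DPersonPatient$columns, `[[`, "", "name")
  expect_true("patientName_name_value" %in% cols)
  # embedding is recorded for the inner archetype too
  emb <- sch$embedded
  expect_true(any(emb$inner_archetype_id ==
                    "openEHR-DEMOGRAPHIC-PARTY_IDENTITY.person_name.v1" &
                    emb$column == "patientName_name_value"))

  # self-referential single-occurrence slot chain -> cycle error
  a <- archetype("openEHR-EHR-CLUSTER.loop_a.v1",
                 list(basic_item("x", "DvText"),
                      slot_item("next", "openEHR-EHR-CLUSTER.loop_b.v1", "1..1")))
  b <- archetype("openEHR-EHR-CLUSTER.loop_b.v1",
                 list(slot_item("back", "openEHR-EHR-CLUSTER.loop_a.v1", "1..1")))
  expect_error(map_schema(tiny_suite(a, b), config = schema_config(standalone_all = TRUE)),
               class = "slot_cycle")
  expect_error(embed_slot(a, a$nodes[[2]], a, tiny_suite(a)), class = "slot_cycle")

  # the same slot as ONE (embedded) and as MANY (FK) covers the same leaves
  target <- archetype("openEHR-EHR-CLUSTER.part.v1",
                      list(basic_item("alpha", "DvText"),
                           basic_item("beta", "DvQuantity")))
  host1 <- archetype("openEHR-EHR-OBSERVATION.holder.v1",
                     list(basic_item("patient", "DvText", "1..1"),
                          slot_item("part", "openEHR-EHR-CLUSTER.part.v1", "1..1")))
  host2 <- archetype("openEHR-EHR-OBSERVATION.holder.v1",
                     list(basic_item("patient", "DvText", "1..1"),
                          slot_item("part", "openEHR-EHR-CLUSTER.part.v1", "1..*")))
  s1 <- map_schema(tiny_suite(host1, target))
  s2 <- map_schema(tiny_suite(host2, target))
  leaves1 <- sort(sub("^.*\\[part\\]/", "", grep("\\[part\\]",
                                                 s1$provenance$node_path, value = TRUE)))
  leaves2 <- sort(s2$provenance$node_path[s2$provenance$archetype_id == target$id])
  expect_identical(paste(leaves1, collapse = "|"), paste(leaves2, collapse = "|"))
  # FK edge sits in the target's table, pointing at the holder
  pt <- s2$tables$CPart
  expect_true(any(vapply(pt$foreign_keys, function(f)
    identical(f$target_table, "OHolder"), TRUE)))
})

test_that("foreign-key topology is one edge per repeating group and acyclic", {
  sch <- fix_schema()
  edges <- list()
  for (t in sch$tables)
    for (f in t$foreign_keys)
      edges[[length(edges) + 1L]] <- c(t$name, f$target_table)
  # each child table has exactly one FK, to its parent's key
  for (t in sch$tables) {
    if (t$origin %in% c("COLLECTION", "MULTI_ITEM"))
      expect_length(t$foreign_keys, 1)
  }
  # acyclicity by repeated leaf elimination
  g <- do.call(rbind, edges)
  nodes <- unique(c(g[, 1], g[, 2]))
  repeat {
    sinks <- setdiff(nodes, g[, 1])
    if (!length(sinks)) break
    keep <- !(g[, 2] %in% sinks) & !(g[, 1] %in% sinks)
    nodes <- setdiff(nodes, sinks)
    g <- g[keep, , drop = FALSE]
    if (!nrow(g)) break
  }
  expect_identical(nrow(g), 0L)
})

test_that("query-item propagation honours template suppression", {
  suite <- fix_suite()
  tpl <- suite$templates[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]]
  tpl$arm$suppressed_propagations <- list(list(group = "[Structure]/[Result]",
                                               query_item = "[receiverOrderIdentifier]"))
  tpls <- suite$templates
  tpls[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]] <- tpl
  sch <- map_schema(suite$archetypes, tpls, suite$eav_maps)
  cols <- vapply(sch$tables$OLabTestGeneralStructureResult$columns, `[[`, "", "name")
  expect_false("OLabTestGeneral_receiverOrderIdentifier_value" %in% cols)
  expect_true("OLabTestGeneral_patient_value" %in% cols)
})

test_that("version merging shares, separates or migrates tables by relationship", {
  o <- tiny_vitals_v1()
  s0 <- map_schema(tiny_suite(o))
  # revision: one shared table, added column nullable
  n_rev <- archetype("openEHR-EHR-OBSERVATION.vitals.v2",
                     c(o$nodes, list(basic_item("spo2", "DvQuantity", "0..1"))))
  s1 <- merge_versions(s0, o, n_rev, suite = tiny_suite(o, n_rev))
  expect_identical(s1$arch_table[[o$id]], s1$arch_table[[n_rev$id]])
  added <- Filter(function(c) identical(c$name, "spo2_magnitude"),
                  s1$tables$OVitals$columns)
  expect_length(added, 1)
  expect_true(added[[1]]$nullable)

  # NEW_VERSION + TABLE_PER_VERSION: second table keeps the version suffix
  n_new <- archetype("openEHR-EHR-OBSERVATION.vitals.v2",
                     list(basic_item("patient", "DvText", "1..1"),
                          basic_item("heartRate", "DvQuantity", "0..1")))
  s2 <- merge_versions(s0, o, n_new, strategy = "TABLE_PER_VERSION",
                       suite = tiny_suite(o, n_new))
  expect_setequal(names(s2$tables), c("OVitals", "OVitalsV2"))

  # SPECIALIZATION: always a distinct table
  n_spec <- archetype("openEHR-EHR-OBSERVATION.vitals-icu.v1", o$nodes,
                      parent = o$id)
  s3 <- merge_versions(s0, o, n_spec, suite = tiny_suite(o, n_spec))
  expect_true("OVitalsIcu" %in% names(s3$tables))
  expect_false(identical(s3$arch_table[[o$id]], s3$arch_table[[n_spec$id]]))

  # MERGE_AND_CONVERT without a conversion for an incompatible not-null
  # column aborts
  n_bad <- archetype("openEHR-EHR-OBSERVATION.vitals.v2",
                     list(basic_item("patient", "DvCodedText", "1..1")))
  expect_error(merge_versions(s0, o, n_bad, strategy = "MERGE_AND_CONVERT",
                              suite = tiny_suite(o, n_bad)),
               class = "missing_conversion")
})
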