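test_that("templates carry the published identification and query items", {
  suite <- fix_suite()
  tpl <- suite$templates[["openEHR-EHR-OBSERVATION.imaging_exam.v1"]]
  arch <- suite$archetypes[[tpl$archetype_id]]
  expect_identical(tpl$arm$identification_item, "[id]")
  qcols <- vapply(tpl$arm$query_items, function(p)
    make_names(arch, p, primary_field_suffix(find_node(arch, p)$node$type)), "")
  expect_setequal(unname(qcols), c("receiverOrderIdentifier_id", "patient_value"))

  pp <- suite$templates[["openEHR-DEMOGRAPHIC-PERSON.person-patient.v1"]]
  parch <- suite$archetypes[[pp$archetype_id]]
  idc <- make_names(parch, pp$arm$identification_item, "id",
                    suite = suite$archetypes)
  expect_identical(idc, "patientIdentifier_identifier_id")
  expect_length(pp$arm$query_items, 0)

  rlt <- suite$templates[["openEHR-EHR-INSTRUCTION.request-lab_test.v1"]]
  expect_identical(rlt$arm$identification_item, "[receiverIdentifier]")
  expect_setequal(rlt$arm$query_items, c("[requestorIdentifier]", "[patient]"))
})

test_that("a document listing two identification items is rejected at parse", {
  bad <- paste0("template_id: t.oet\narchetype_id: openEHR-EHR-OBSERVATION.x.v1\n",
                "arm:\n  identification_item: ['[a]', '[b]']\n")
  expect_error(parse_template(bad), class = "duplicate_idi")
})

test_that("validation flags collections and repeating items in ARM roles", {
  suite <- fix_suite()
  gen <- suite$archetypes[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]]
  # collection as identification item
  t1 <- template("t1.oet", gen$id,
                 arm_constraints(identification_item = "[Structure]"))
  v1 <- validate_template(t1, gen, suite$archetypes)
  expect_true("collection_as_constraint" %in% v1$code)
  # identification item inside a repeating group violates 0..1/1..1
  t2 <- template("t2.oet", gen$id,
                 arm_constraints(identification_item =
                                   "[Structure]/[Result]/[Test item]"))
  v2 <- validate_template(t2, gen, suite$archetypes)
  expect_true("idi_occurrence" %in% v2$code)
  # slot as query item
  t3 <- template("t3.oet", gen$id,
                 arm_constraints(query_items = "[annotation]"))
  expect_true("collection_as_constraint" %in%
                validate_template(t3, gen, suite$archetypes)$code)
  # loosening override
  t4 <- template("t4.oet", gen$id,
                 optionality_overrides = list("[patient]" = "0..1"))
  expect_true("loosening_override" %in%
                validate_template(t4, gen, suite$archetypes)$code)
})

test_that("every fixture template validates cleanly against its archetype", {
  suite <- fix_suite()
  for (tpl in suite$templates) {
    v <- validate_template(tpl, suite$archetypes[[tpl$archetype_id]],
                           suite$archetypes)
    expect_identical(nrow(v), 0L, info = tpl$template_id)
  }
})

test_that("adding a violation-free constraint never introduces violations", {
  suite <- fix_suite()
  gen <- suite$archetypes[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]]
  base <- suite$templates[[gen$id]]
  expect_identical(nrow(validate_template(base, gen, suite$archetypes)), 0L)
  grown <- base
  grown$arm$query_items <- c(grown$arm$query_items, "[testDateTime]")
  expect_identical(nrow(validate_template(grown, gen, suite$archetypes)), 0L)
})

test_that("EAV mapping documents parse, validate and round-trip", {
  suite <- fix_suite()
  # bare element sequence in the printed table style
  frag <- paste0(
    '<eav name = "openEHR-EHR-OBSERVATION.lab_test-general.v1"> </eav>',
    '<eavAttributeName name = "[White cell count]" set = "en">',
    ' [Test item]/value/value</eavAttributeName>',
    '<eavAttributeField name = "[White cell count]/value/magnitude">',
    ' [Result]/value/value</eavAttributeField>',
    '<eavAttributeField name = "[White cell count]/value/units">',
    ' [Result unit]/value/value</eavAttributeField>')
  m <- parse_eav_mapping(frag, "openEHR-EHR-OBSERVATION.lab_test-full_blood_count.v1")
  expect_identical(m$generalized_archetype_id,
                   "openEHR-EHR-OBSERVATION.lab_test-general.v1")
  expect_identical(m$name_entries$source, "[White cell count]")
  expect_identical(m$name_entries$set, "en")
  expect_identical(m$name_entries$target, "[Test item]/value/value")
  expect_setequal(m$field_entries$target,
                  c("[Result]/value/value", "[Result unit]/value/value"))

  # vacuous mapping: an <eav> element alone
  m0 <- parse_eav_mapping('<eav name="openEHR-EHR-OBSERVATION.lab_test-general.v1"></eav>',
                          "x")
  expect_identical(nrow(m0$name_entries), 0L)
  expect_identical(nrow(m0$field_entries), 0L)

  expect_error(parse_eav_mapping("<eavMapping><bogus/></eavMapping>"),
               class = "unknown_element")
  expect_error(parse_eav_mapping('<eavMapping><eavAttributeName set="en">x</eavAttributeName></eavMapping>'),
               class = "missing_attribute")

  # round-trip over every shipped mapping
  for (mm in suite$eav_maps) {
    rt <- parse_eav_mapping(serialize_eav_mapping(mm))
    expect_true(json_equal(mm[], rt[]), info = mm$specialized_archetype_id)
  }
})

test_that("every specialized analyte maps onto the name/result/unit triple", {
  suite <- fix_suite()
  gen <- suite$archetypes[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]]
  for (m in suite$eav_maps) {
    spec_arch <- suite$archetypes[[m$specialized_archetype_id]]
    expect_identical(nrow(validate_eav_mapping(m, spec_arch, gen)), 0L,
                     info = m$specialized_archetype_id)
    items <- unique(vapply(m$field_entries$source,
                           function(p) basename_path(eav_item_path(p)), ""))
    for (it in items) {
      rows <- m$field_entries[vapply(m$field_entries$source, function(p)
        basename_path(eav_item_path(p)), "") == it, ]
      expect_setequal(rows$target,
                      c("[Result]/value/value", "[Result unit]/value/value"))
      expect_true(it %in% vapply(m$name_entries$source, basename_path, ""))
    }
  }
})
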