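test_that("parse-serialize-parse is the identity on every fixture archetype", {
  for (a in fix_suite()$archetypes) {
    reparsed <- parse_archetype(serialize_archetype(a))
    expect_true(arch_equal(a, reparsed), info = a$id)
  }
})

test_that("the generalized lab archetype specializes the base lab test", {
  suite <- fix_suite()$archetypes
  gen <- suite[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]]
  expect_identical(gen$parent, "openEHR-EHR-OBSERVATION.lab_test.v1")
  # the three added result items live in one multiple-occurrence group
  grp <- find_node(gen, "[Structure]/[Result]")$node
  expect_identical(grp$kind, "collection")
  expect_true(occ_many(grp$occurrence))
  expect_setequal(vapply(grp$children, `[[`, "", "name"),
                  c("Test item", "Result", "Result unit"))
  base <- suite[[gen$parent]]
  added <- setdiff(vapply(arch_nodes_flat(gen), `[[`, "", "path"),
                   vapply(arch_nodes_flat(base), `[[`, "", "path"))
  expect_setequal(added, c("[id]", "[Structure]/[Result]",
                           "[Structure]/[Result]/[Test item]",
                           "[Structure]/[Result]/[Result]",
                           "[Structure]/[Result]/[Result unit]"))
})

test_that("malformed archetype documents raise the documented errors", {
  expect_error(parse_archetype("archetype_id: openEHR-EHR-OBSERVATION.x.v1\nnodes: []"),
               class = "empty_archetype")
  expect_error(parse_archetype(": bad: [yaml"), class = "syntax_error")
  expect_error(archetype("openEHR-EHR-OBSERVATION.x.v1",
                         list(basic_item("a", "DvText"),
                              basic_item("a", "DvText"))),
               class = "duplicate_path")
  expect_error(basic_item("a", "NotAType"), class = "unknown_basic_type")
  expect_error(parse_archetype(paste0(
    "archetype_id: openEHR-EHR-OBSERVATION.x-y.v1\n",
    "parent: openEHR-EHR-OBSERVATION.x.v1\n",
    "nodes:\n- {name: a, type: DvText}\n"),
    known_ids = "openEHR-EHR-OBSERVATION.z.v1"),
    class = "dangling_parent")
  expect_error(occurrence("2..3"), class = "bad_occurrence")
})

test_that("version relationships classify per the compatibility table", {
  suite <- fix_suite()$archetypes
  old <- suite[["openEHR-EHR-OBSERVATION.lab_test.v1"]]
  # identical definitions are trivially compatible
  for (a in suite) expect_identical(classify_relationship(a, a), "REVISION")
  # pure addition of an optional item keeps old data valid
  grown <- archetype("openEHR-EHR-OBSERVATION.lab_test.v2",
                     c(old$nodes, list(basic_item("note", "DvText", "0..1"))))
  expect_identical(classify_relationship(old, grown), "REVISION")
  # widening an upper bound is an expansion, still a revision
  wid <- old$nodes
  wid[[1]]$occurrence <- occurrence("0..*")
  expect_identical(classify_relationship(
    old, archetype("openEHR-EHR-OBSERVATION.lab_test.v2", wid)), "REVISION")
  # mandatory item made optional breaks compatibility
  opt <- old$nodes
  opt[[2]]$occurrence <- occurrence("0..1")   # patient was 1..1
  expect_identical(classify_relationship(
    old, archetype("openEHR-EHR-OBSERVATION.lab_test.v2", opt)), "NEW_VERSION")
  # changed basic type breaks compatibility
  typ <- old$nodes
  typ[[1]] <- basic_item("receiverOrderIdentifier", "DvIdentifier", "0..1")
  expect_identical(classify_relationship(
    old, archetype("openEHR-EHR-OBSERVATION.lab_test.v2", typ)), "NEW_VERSION")
  # concept extension with equal-or-stronger constraints
  expect_identical(classify_relationship(
    old, suite[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]]),
    "SPECIALIZATION")
  expect_identical(classify_relationship(
    old, suite[["openEHR-EHR-OBSERVATION.lab_test-blood_gases.v1"]]),
    "SPECIALIZATION")
  expect_error(classify_relationship(
    old, suite[["openEHR-EHR-OBSERVATION.imaging_exam.v1"]]),
    class = "no_lineage")
})
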