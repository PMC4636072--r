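test_that("identifiers derive from archetype, path and field per naming rules", {
  suite <- fix_suite()$archetypes
  gen <- suite[["openEHR-EHR-OBSERVATION.lab_test-general.v1"]]
  expect_identical(make_names(gen), "OLabTestGeneral")
  expect_identical(make_names(gen, "[Structure]/[Result]"),
                   "OLabTestGeneralStructureResult")
  pat <- suite[["openEHR-DEMOGRAPHIC-PERSON.person-patient.v1"]]
  expect_identical(make_names(pat, "[patientIdentifier]/[identifier]", "id",
                              suite = suite),
                   "patientIdentifier_identifier_id")
  # a trailing repetition of the item name collapses
  img <- suite[["openEHR-EHR-OBSERVATION.imaging_exam.v1"]]
  expect_identical(make_names(img, "[id]", "id"), "id")
  expect_identical(make_names(img, "[patient]", "value"), "patient_value")
  # collection segments are omitted from column names, kept in table names
  bg <- suite[["openEHR-EHR-OBSERVATION.lab_test-blood_gases.v1"]]
  expect_identical(make_names(bg, "[Structure]/[PaO2]", "magnitude"),
                   "PaO2_magnitude")
})

test_that("over-long names shorten deterministically and stay unique", {
  long <- paste(rep("VeryLongConceptSegment", 20), collapse = "")
  s <- shorten_identifier(long, 64L)
  expect_identical(nchar(s), 64L)
  expect_identical(s, shorten_identifier(long, 64L))
  expect_identical(shorten_identifier("short", 64L), "short")

  set.seed(42)
  n <- 20000L
  alphabet <- c(letters, LETTERS, 0:9)
  names <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, 80, replace = TRUE), collapse = ""), "")
  shortened <- vapply(names, shorten_identifier, "", limit = 64L)
  expect_true(all(nchar(shortened) == 64L))
  expect_identical(anyDuplicated(shortened), 0L)
})
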