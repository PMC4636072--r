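test_that("registry holds exactly the published basic types with their fields", {
  expect_setequal(basic_type_names(),
                  c("CodePhrase", "DvBoolean", "DvCodedText", "DvCount",
                    "DvDateTime", "DvEHRURI", "DvIdentifier", "DvMultimedia",
                    "DvProportion", "DvQuantity", "DvText", "DvURI",
                    "GenericID", "Link"))
  spec <- basic_type_spec("DvQuantity")
  expect_equal(vapply(spec, `[[`, "", "field"), c("magnitude", "units"))
  expect_equal(vapply(spec, `[[`, "", "kind"), c("FLOAT", "NVARCHAR"))
  expect_equal(basic_type_spec("DvBoolean")[[1]]$kind, "INTEGER")
  expect_equal(basic_type_spec("DvProportion")[[1]]$field, "precision")
  expect_error(basic_type_spec("DvFoo"), class = "unknown_basic_type")
})

test_that("field columns resolve reference chains to primitive storage kinds", {
  q <- resolve_field_columns("DvQuantity")
  expect_equal(q$suffix, c("magnitude", "units"))
  expect_equal(q$kind, c("FLOAT", "NVARCHAR"))

  ct <- resolve_field_columns("DvCodedText")
  expect_equal(ct$suffix, "definingCode_code")
  expect_equal(ct$kind, "NVARCHAR")

  expect_equal(resolve_field_columns("DvBoolean"),
               data.frame(suffix = "value", kind = "INTEGER",
                          stringsAsFactors = FALSE))

  # two-hop chain: DvMultimedia -> DvURI -> primitive
  mm <- resolve_field_columns("DvMultimedia")
  expect_equal(mm$suffix, "uri_value")
  expect_equal(mm$kind, "NVARCHAR")
  lk <- resolve_field_columns("Link")
  expect_equal(lk$suffix, "target_value")
})

test_that("resolution is total and always reaches a primitive", {
  for (tn in basic_type_names()) {
    r <- resolve_field_columns(tn)
    expect_gt(nrow(r), 0)
    expect_true(all(r$kind %in% c("NVARCHAR", "INTEGER", "FLOAT")),
                info = tn)
  }
})

test_that("DvProportion numerator/denominator appear only behind the switch", {
  expect_equal(resolve_field_columns("DvProportion")$suffix, "precision")
  ext <- resolve_field_columns("DvProportion", dv_proportion_extended = TRUE)
  expect_equal(ext$suffix, c("precision", "numerator", "denominator"))
  expect_equal(ext$kind, c("INTEGER", "FLOAT", "FLOAT"))
})
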