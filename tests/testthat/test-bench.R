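test_that("the benchmark enumerates exactly the published query ids", {
  b <- loaded_backends()
  qs <- build_queries(fix_suite(), b$ds)
  ids <- vapply(qs, `[[`, "", "id")
  expect_identical(ids, c("1.1", "1.2", "1.3", "2.1", "2.2", "2.3",
                          "3.1", "3.2", "3.3", "4.1", "4.2", "4.3",
                          "5.1", "5.2", "5.3", "6.1", "6.2", "6.3",
                          "7.1", "7.2"))
  expect_length(qs, 20)
})

test_that("threshold searches carry the published condition sets", {
  b <- loaded_backends()
  qs <- build_queries(fix_suite(), b$ds)
  byid <- stats::setNames(qs, vapply(qs, `[[`, "", "id"))
  q63 <- byid[["6.3"]]$spec$clauses[[1]]
  expect_length(q63$conditions, 5)
  expect_setequal(vapply(q63$conditions, `[[`, "", "path"),
                  paste0("[Structure]/[", c("PaO2", "PaCO2", "Arterial pH",
                                            "SaO2", "CaO2"), "]"))
  expect_true(all(vapply(q63$conditions, `[[`, "", "op") == ">="))
  # five clauses across five lab panels, intersected at subject level
  q72 <- byid[["7.2"]]$spec
  expect_length(q72$clauses, 5)
  expect_identical(q72$grouping, "subject")
  # the average-scenario work-list query binds the clinician nearest the
  # dataset mean patient load
  pc <- table(b$ds$meta$patients$clinician)
  target <- byid[["1.2"]]$spec$clauses[[1]]$conditions[[1]]$value
  expect_identical(unname(abs(pc[target] - mean(pc))), min(abs(pc - mean(pc))))
})

test_that("zero repetitions are rejected", {
  b <- loaded_backends()
  qs <- build_queries(fix_suite(), b$ds)
  expect_error(run_benchmark(qs[1], list(arm = b$arm), repetitions = 0),
               class = "bad_params")
})

test_that("the benchmark report covers every query and backend with agreeing digests", {
  b <- loaded_backends()
  qs <- build_queries(fix_suite(), b$ds)
  rep <- run_benchmark(qs, list(arm = b$arm, nodepath = b$np),
                       repetitions = 2L, inner = 1L, dataset_descriptor = "small")
  res <- rep$results
  expect_identical(nrow(res), 40L)
  expect_setequal(unique(res$backend), c("arm", "nodepath"))
  for (qid in unique(res$query)) {
    d <- unique(res$digest[res$query == qid])
    expect_length(d, 1)
  }
  expect_true(all(res$mean_ms >= 0))
  expect_setequal(names(rep$footprints), c("arm", "nodepath"))
  # a report survives the JSON/CSV writers
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_report(rep, jf, cf)
  expect_true(file.exists(jf) && file.exists(cf))
  expect_identical(nrow(utils::read.csv(cf)), 40L)
})
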