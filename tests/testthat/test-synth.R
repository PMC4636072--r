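test_that("generation is byte-identical under a fixed seed", {
  p <- dataset_params(seed = 5, n_patients = 15)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  j1 <- vapply(d1$instances, instance_to_json, "")
  j2 <- vapply(d2$instances, instance_to_json, "")
  expect_identical(j1, j2)
  # a different seed moves the stream
  d3 <- generate_dataset(dataset_params(seed = 6, n_patients = 15))
  expect_false(identical(j1, vapply(d3$instances, instance_to_json, "")))
})

test_that("count maxima are never exceeded", {
  for (seed in c(3, 4)) {
    ds <- generate_dataset(dataset_params(seed = seed, n_patients = 60))
    p <- ds$params
    ex_per_pat <- table(ds$meta$exams$patient)
    expect_lte(max(ex_per_pat), p$imaging_per_patient$max)   # at most 26 exams
    expect_lte(max(ds$meta$exams$images), p$images_per_exam$max)
    lab_per_pat <- table(ds$meta$labs$patient)
    expect_lte(max(lab_per_pat), p$labs_per_patient$max)
    gl <- ds$meta$labs[ds$meta$labs$panel == "general", ]
    if (nrow(gl)) expect_lte(max(gl$results), p$results_per_lab$max)
    pat_per_clin <- table(ds$meta$patients$clinician)
    expect_lte(max(pat_per_clin), p$patients_per_clinician$max)
  }
})

test_that("empirical count means track the configured targets at desk scale", {
  imgs <- labs <- res <- numeric()
  for (seed in 1:10) {
    ds <- generate_dataset(dataset_params(seed = seed))
    imgs <- c(imgs, ds$meta$exams$images)
    labs <- c(labs, as.vector(table(ds$meta$labs$patient)))
    gl <- ds$meta$labs[ds$meta$labs$panel == "general", ]
    res <- c(res, gl$results)
  }
  p <- dataset_params()
  expect_lt(abs(mean(imgs) - p$images_per_exam$mean) / p$images_per_exam$mean, 0.3)
  expect_lt(abs(mean(labs) - p$labs_per_patient$mean) / p$labs_per_patient$mean, 0.3)
  expect_lt(abs(mean(res) - p$results_per_lab$mean) / p$results_per_lab$mean, 0.3)
})

test_that("every generated instance validates against its archetype", {
  suite <- fix_suite()$archetypes
  ds <- small_dataset()
  for (i in ds$instances)
    expect_silent(validate_instance(i, suite[[i$archetype_id]], suite))
})

test_that("infeasible parameters are rejected", {
  expect_error(dataset_params(images_per_exam = list(min = 10, mean = 5, max = 3)),
               class = "bad_params")
  expect_error(dataset_params(scale = 0), class = "bad_params")
})

test_that("the first threshold search selects a proper nonempty patient subset", {
  b <- loaded_backends(seed = 7, n = 25)
  qs <- build_queries(fix_suite(), b$ds)
  q61 <- Filter(function(q) q$id == "6.1", qs)[[1]]
  r <- run_query(b$arm, q61$spec)
  bg_pat <- unique(b$ds$meta$labs$patient[b$ds$meta$labs$panel == "blood_gases"])
  expect_gt(length(r$keys), 0)
  expect_lt(length(r$keys), length(bg_pat))
  expect_true(all(r$keys %in% bg_pat))
})
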