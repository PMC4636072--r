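# The seven-test benchmark: five data-retrieving tests bound to entities at
# the distribution extremes of the loaded dataset (min / nearest-average /
# max variants) and two patient-searching tests with fixed clinical
# thresholds. Result-set equality across backends is asserted before any
# timing is reported; timings are ordinal evidence only — absolute numbers
# are hardware-bound.

bench_query <- function(id, group, spec, note = "") {
  list(id = id, group = group, spec = spec, note = note)
}

pick_min_avg_max <- function(df, key_col, count_col) {
  agg <- df[order(df[[count_col]]), ]
  m <- mean(df[[count_col]])
  list(min = agg[[key_col]][[1L]],
       avg = agg[[key_col]][[which.min(abs(agg[[count_col]] - m))]],
       max = agg[[key_col]][[nrow(agg)]])
}

#' Build the benchmark query list from a loaded dataset
#'
#' Tests 1-5 (work-list and data-retrieving): patients per clinician,
#' imaging exams per patient, images per exam, lab tests per patient,
#' results per generalized lab test — each bound to the entity with the
#' minimum / nearest-average / maximum count in `dataset$meta`. Test 6:
#' blood-gas threshold searches with 1, 3 and 5 conditions. Test 7:
#' cross-panel subject searches with 3 and 5 conditions.
#'
#' @param suite Fixture suite.
#' @param dataset Result of [generate_dataset()].
#' @return List of benchmark queries (ids 1.1-7.2).
#' @export
build_queries <- function(suite, dataset) {
  meta <- dataset$meta
  qs <- list()
  add <- function(id, group, spec, note = "")
    qs[[length(qs) + 1L]] <<- bench_query(id, group, spec, note)

  # test 1: all patients of one clinician
  pc <- stats::aggregate(patient ~ clinician, meta$patients, length)
  b1 <- pick_min_avg_max(pc, "clinician", "patient")
  for (v in c("min", "avg", "max"))
    add(paste0("1.", match(v, c("min", "avg", "max"))), 1L,
        query_spec(query_clause("openEHR-DEMOGRAPHIC-PERSON.person-patient.v1",
                                list(condition("[clinician]", "=", b1[[v]]))),
                   projection = "ALL"), v)

  # test 2: all imaging exam requests of one patient
  ep <- stats::aggregate(exam ~ patient, meta$exams, length)
  b2 <- pick_min_avg_max(ep, "patient", "exam")
  for (v in c("min", "avg", "max"))
    add(paste0("2.", match(v, c("min", "avg", "max"))), 2L,
        query_spec(query_clause("openEHR-EHR-INSTRUCTION.request-imaging_exam.v1",
                                list(condition("[patient]", "=", b2[[v]]))),
                   projection = "ALL"), v)

  # test 3: all images of one exam
  b3 <- pick_min_avg_max(meta$exams, "exam", "images")
  for (v in c("min", "avg", "max"))
    add(paste0("3.", match(v, c("min", "avg", "max"))), 3L,
        query_spec(query_clause("openEHR-EHR-OBSERVATION.imaging_exam.v1",
                                list(condition("[id]", "=", b3[[v]],
                                               suffix = "id"))),
                   projection = "[Image details]"), v)

  # test 4: all lab test requests of one patient
  lp <- stats::aggregate(panel ~ patient, meta$labs, length)
  b4 <- pick_min_avg_max(lp, "patient", "panel")
  for (v in c("min", "avg", "max"))
    add(paste0("4.", match(v, c("min", "avg", "max"))), 4L,
        query_spec(query_clause("openEHR-EHR-INSTRUCTION.request-lab_test.v1",
                                list(condition("[patient]", "=", b4[[v]]))),
                   projection = "ALL"), v)

  # test 5: all results of one generalized lab test
  gl <- meta$labs[meta$labs$panel == "general", , drop = FALSE]
  if (!nrow(gl)) abort2("fixture_mismatch", "dataset holds no generalized lab tests")
  b5 <- pick_min_avg_max(gl, "lab", "results")
  for (v in c("min", "avg", "max"))
    add(paste0("5.", match(v, c("min", "avg", "max"))), 5L,
        query_spec(query_clause("openEHR-EHR-OBSERVATION.lab_test-general.v1",
                                list(condition("[id]", "=", b5[[v]],
                                               suffix = "id"))),
                   projection = "[Structure]/[Result]"), v)

  # test 6: blood-gas threshold searches (1, 3, 5 conditions)
  bg <- "openEHR-EHR-OBSERVATION.lab_test-blood_gases.v1"
  c61 <- list(condition("[Structure]/[PaO2]", ">=", 129))
  c62 <- c(c61, list(condition("[Structure]/[PaCO2]", ">=", 27),
                     condition("[Structure]/[Arterial pH]", ">=", 7.3)))
  c63 <- c(c62, list(condition("[Structure]/[SaO2]", ">=", 99),
                     condition("[Structure]/[CaO2]", ">=", 17)))
  add("6.1", 6L, query_spec(query_clause(bg, c61), grouping = "subject"))
  add("6.2", 6L, query_spec(query_clause(bg, c62), grouping = "subject"))
  add("6.3", 6L, query_spec(query_clause(bg, c63), grouping = "subject"))

  # test 7: cross-panel subject searches (3 and 5 conditions)
  fbc <- "openEHR-EHR-OBSERVATION.lab_test-full_blood_count.v1"
  lf <- "openEHR-EHR-OBSERVATION.lab_test-liver_function.v1"
  th <- "openEHR-EHR-OBSERVATION.lab_test-thyroid.v1"
  ue <- "openEHR-EHR-OBSERVATION.lab_test-urea_and_electrolytes.v1"
  cl71 <- list(
    query_clause(bg, list(condition("[Structure]/[PaO2]", ">=", 229))),
    query_clause(fbc, list(condition("[Structure]/[Red cell count]", ">=", 2))),
    query_clause(lf, list(condition("[Structure]/[Alkaline phosphatase]", ">=", 50))))
  cl72 <- c(cl71, list(
    query_clause(th, list(condition("[Structure]/[Thyroid stimulating hormone]",
                                    ">=", 0.3))),
    query_clause(ue, list(condition("[Structure]/[Sodium]", ">=", 140)))))
  add("7.1", 7L, query_spec(cl71, grouping = "subject"))
  add("7.2", 7L, query_spec(cl72, grouping = "subject"))
  qs
}

run_on_backend <- function(store, spec) {
  if (inherits(store, "np_store")) np_run_query(store, spec)
  else run_query(store, spec)
}

#' Run the benchmark over one or more backends
#'
#' Each query runs `repetitions` times per backend; every repetition
#' re-executes the query from scratch (fresh result structures; a `gc()`
#' precedes each timing to curb collector noise — the in-process analogue of
#' disabling the database cache between runs). Result-set digests must agree
#' across backends for every query before timings are reported.
#'
#' @param queries From [build_queries()].
#' @param backends Named list of stores, all loaded with the identical
#'   dataset (e.g. `list(arm = ..., nodepath = ...)`).
#' @param repetitions Repetitions per query (default 10; must be positive).
#' @param inner Executions per timed repetition (timer-resolution guard).
#' @return A `bench_report`: data.frame `results` (query, backend, mean_ms,
#'   median_ms, result_count, digest), `footprints`, `dataset_descriptor`.
#' @export
run_benchmark <- function(queries, backends, repetitions = 10L, inner = 3L,
                          dataset_descriptor = "") {
  if (!is.numeric(repetitions) || repetitions < 1L)
    abort2("bad_params", "repetitions must be a positive integer")
  rows <- list()
  for (q in queries) {
    digests <- character()
    for (bn in names(backends)) {
      st <- backends[[bn]]
      rs <- run_on_backend(st, q$spec)
      digests[[bn]] <- rs$digest
      times <- numeric(repetitions)
      for (r in seq_len(repetitions)) {
        gc(FALSE)
        t0 <- proc.time()[["elapsed"]]
        for (k in seq_len(inner)) rs2 <- run_on_backend(st, q$spec)
        times[[r]] <- (proc.time()[["elapsed"]] - t0) / inner
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query = q$id, group = q$group, backend = bn,
        repetitions = repetitions,
        mean_ms = mean(times) * 1000, median_ms = stats::median(times) * 1000,
        result_count = length(rs$keys), digest = rs$digest,
        stringsAsFactors = FALSE)
    }
    if (length(unique(digests)) != 1L)
      abort2("digest_mismatch",
             "backends disagree on query %s: %s", q$id,
             paste(names(digests), digests, sep = "=", collapse = ", "))
  }
  results <- do.call(rbind, rows)
  footprints <- vapply(backends, db_size_bytes, 0)
  structure(list(results = results, footprints = footprints,
                 dataset_descriptor = dataset_descriptor),
            class = "bench_report")
}

#' Write a benchmark report as JSON and CSV
#' @param report From [run_benchmark()].
#' @param json_path,csv_path Output files (NULL to skip either).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(dataset = report$dataset_descriptor,
                              footprints = as.list(report$footprints),
                              results = report$results),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataFrame = "rows")
  if (!is.null(csv_path))
    utils::write.csv(report$results, csv_path, row.names = FALSE)
  invisible(report)
}
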