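# Seeded synthetic dataset generator emulating the integrated-viewer
# workload shape: patients assigned to clinicians, imaging exam requests and
# exams with image series, lab test requests and lab tests (a mix of
# specialized panels and the generalized form with repeated result items).
#
# Per-entity counts follow log-normal distributions truncated to [min, max]
# with the mean matched to the configured average (the published workload
# averages, scaled down for desk-scale runs); the heavy right tail mirrors
# the large printed maxima.

#' Dataset generation parameters
#'
#' Defaults are the desk-scale study conditions: 200 patients and a 0.05
#' scale factor on the large per-entity counts (images per exam, lab tests
#' per patient, results per generalized lab test). Scaled means keep a floor
#' of 2 so the distributions stay non-degenerate. `min <= mean <= max` is
#' required for every distribution and the seed fixes all randomness.
#'
#' @param seed Integer seed.
#' @param n_patients Number of patients.
#' @param n_clinicians Number of clinicians (default about one per 7
#'   patients, matching the average daily patient load).
#' @param scale Scale factor applied to the scalable count distributions.
#' @param patients_per_clinician,imaging_per_patient,images_per_exam,labs_per_patient,results_per_lab
#'   Count distributions `list(min, mean, max)`; the last three scale.
#' @param panel_mix Weights over the lab panels plus `general`.
#' @param date_range Two dates (ISO) bounding event datetimes.
#' @return A `dataset_params` list.
#' @export
dataset_params <- function(seed = 1L,
                           n_patients = 200L,
                           n_clinicians = NULL,
                           scale = 0.05,
                           patients_per_clinician = list(min = 1, mean = 7, max = 50),
                           imaging_per_patient = list(min = 1, mean = 3, max = 26),
                           images_per_exam = list(min = 1, mean = 363, max = 10664),
                           labs_per_patient = list(min = 1, mean = 23, max = 425),
                           results_per_lab = list(min = 1, mean = 168, max = 4477),
                           panel_mix = c(blood_gases = 0.12,
                                         full_blood_count = 0.18,
                                         liver_function = 0.15,
                                         thyroid = 0.10,
                                         urea_and_electrolytes = 0.15,
                                         general = 0.30),
                           date_range = c("2014-01-01", "2014-12-31")) {
  if (scale <= 0) abort2("bad_params", "scale must be positive")
  for (d in list(patients_per_clinician, imaging_per_patient, images_per_exam,
                 labs_per_patient, results_per_lab)) {
    if (!(d$min <= d$mean && d$mean <= d$max))
      abort2("bad_params", "count distribution requires min <= mean <= max")
  }
  n_clinicians <- n_clinicians %||% max(1L, ceiling(n_patients / 7))
  scaled <- function(d) list(min = d$min,
                             mean = max(2, d$mean * scale),
                             max = max(d$min, round(d$max * scale)))
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_clinicians = as.integer(n_clinicians), scale = scale,
                 patients_per_clinician = patients_per_clinician,
                 imaging_per_patient = imaging_per_patient,
                 images_per_exam = scaled(images_per_exam),
                 labs_per_patient = scaled(labs_per_patient),
                 results_per_lab = scaled(results_per_lab),
                 panel_mix = panel_mix / sum(panel_mix),
                 date_range = date_range),
            class = "dataset_params")
}

# integer draws from a log-normal truncated to [min, max], mean matched
rtrunc_count <- function(n, dist, sigma = 0.8) {
  if (n == 0L) return(integer())
  mu <- log(dist$mean) - sigma^2 / 2
  out <- integer(n)
  need <- seq_len(n)
  for (iter in 1:50) {
    draw <- as.integer(round(exp(stats::rnorm(length(need), mu, sigma))))
    ok <- draw >= dist$min & draw <= dist$max
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need)) out[need] <- as.integer(round(pmin(pmax(dist$mean, dist$min),
                                                       dist$max)))
  out
}

rand_datetime <- function(n, range) {
  t0 <- as.numeric(as.POSIXct(paste0(range[[1L]], " 00:00:00"), tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(paste0(range[[2L]], " 23:59:59"), tz = "UTC"))
  format(as.POSIXct(stats::runif(n, t0, t1), origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S")
}

txt <- function(v) list(value = as.character(v))

#' Generate a synthetic dataset
#'
#' Deterministic under the seed: the same parameters always yield the same
#' instance stream. Patients come first (so identification targets exist
#' before their dependents), then per patient the imaging requests/exams and
#' lab requests/tests in id order.
#'
#' @param params [dataset_params()].
#' @return List with `instances` (store-order list of instances) and `meta`
#'   (data.frames of entity counts used for benchmark query binding).
#' @export
generate_dataset <- function(params = dataset_params()) {
  stopifnot(inherits(params, "dataset_params"))
  set.seed(params$seed)
  panels <- analyte_panels()
  out <- list(); oi <- 0L
  emit <- function(inst) { oi <<- oi + 1L; out[[oi]] <<- inst }

  clin_ids <- sprintf("C%03d", seq_len(params$n_clinicians))
  # target loads drawn from the per-clinician distribution, used as
  # assignment weights; the max bound is enforced by capping
  loads <- rtrunc_count(params$n_clinicians, params$patients_per_clinician)
  assigned <- integer(params$n_clinicians)
  pat_clin <- character(params$n_patients)
  for (i in seq_len(params$n_patients)) {
    open <- which(assigned < params$patients_per_clinician$max)
    j <- if (length(open) == 1L) open
    else sample(open, 1L, prob = loads[open] + 0.1)
    assigned[[j]] <- assigned[[j]] + 1L
    pat_clin[[i]] <- clin_ids[[j]]
  }

  pat_ids <- sprintf("P%06d", seq_len(params$n_patients))
  sexes <- sample(c("M", "F"), params$n_patients, replace = TRUE)
  for (i in seq_len(params$n_patients)) {
    emit(archetype_instance("openEHR-DEMOGRAPHIC-PERSON.person-patient.v1", list(
      patientIdentifier = list(identifier = list(id = pat_ids[[i]]),
                               type = txt("MRN")),
      patientName = list(name = txt(paste0("Patient ", pat_ids[[i]]))),
      details = list(sex = list(definingCode_code = sexes[[i]])),
      clinician = txt(pat_clin[[i]]))))
  }

  n_exams_per_pat <- rtrunc_count(params$n_patients, params$imaging_per_patient)
  n_labs_per_pat <- rtrunc_count(params$n_patients, params$labs_per_patient)

  exam_counter <- 0L; lab_counter <- 0L
  meta_exam <- list(); meta_lab <- list()
  for (i in seq_len(params$n_patients)) {
    pid <- pat_ids[[i]]; cid <- pat_clin[[i]]
    # imaging: request + exam pairs
    n_ex <- n_exams_per_pat[[i]]
    img_counts <- rtrunc_count(n_ex, params$images_per_exam)
    for (k in seq_len(n_ex)) {
      exam_counter <- exam_counter + 1L
      rq <- sprintf("RQI%06d", exam_counter)
      ex <- sprintf("EX%06d", exam_counter)
      dt <- rand_datetime(1L, params$date_range)
      emit(archetype_instance("openEHR-EHR-INSTRUCTION.request-imaging_exam.v1",
                              list(id = list(id = rq),
                                   requestorIdentifier = txt(cid),
                                   receiverIdentifier = txt("RAD"),
                                   patient = txt(pid),
                                   requestDateTime = txt(dt),
                                   receiver = list(name = txt("Radiology")))))
      n_img <- img_counts[[k]]
      images <- lapply(seq_len(n_img), function(m) list(
        image = list(uri_value = sprintf("pacs://%s/%d", ex, m)),
        imageType = txt("DICOM")))
      emit(archetype_instance("openEHR-EHR-OBSERVATION.imaging_exam.v1", list(
        id = list(id = ex),
        receiverOrderIdentifier = list(id = rq),
        patient = txt(pid),
        examDateTime = txt(dt),
        `Image details` = images)))
      meta_exam[[exam_counter]] <- data.frame(exam = ex, patient = pid,
                                              images = n_img,
                                              stringsAsFactors = FALSE)
    }
    # labs: request + test pairs; panel drawn from the mix
    n_lb <- n_labs_per_pat[[i]]
    panel_draw <- sample(names(params$panel_mix), n_lb, replace = TRUE,
                         prob = params$panel_mix)
    res_counts <- rtrunc_count(n_lb, params$results_per_lab)
    for (k in seq_len(n_lb)) {
      lab_counter <- lab_counter + 1L
      rq <- sprintf("RQL%06d", lab_counter)
      dt <- rand_datetime(1L, params$date_range)
      emit(archetype_instance("openEHR-EHR-INSTRUCTION.request-lab_test.v1",
                              list(receiverIdentifier = txt(rq),
                                   requestorIdentifier = txt(cid),
                                   patient = txt(pid),
                                   requestDateTime = txt(dt))))
      pn <- panel_draw[[k]]
      if (pn == "general") {
        lt <- sprintf("LT%06d", lab_counter)
        pool <- unlist(lapply(panels, function(p) names(p$analytes)))
        pool_meta <- do.call(c, lapply(panels, function(p) p$analytes))
        picks <- sample(seq_along(pool), res_counts[[k]], replace = TRUE)
        reps <- lapply(picks, function(pi) {
          a <- pool_meta[[pi]]
          list(`Test item` = txt(pool[[pi]]),
               Result = txt(formatC(stats::rnorm(1L, a$mean, a$sd),
                                    digits = 15, format = "g")),
               `Result unit` = txt(a$units))
        })
        emit(archetype_instance("openEHR-EHR-OBSERVATION.lab_test-general.v1",
                                list(id = list(id = lt),
                                     receiverOrderIdentifier = txt(rq),
                                     patient = txt(pid),
                                     testDateTime = txt(dt),
                                     Structure = list(`Test name` = txt("General panel"),
                                                      Result = reps))))
        meta_lab[[lab_counter]] <- data.frame(lab = lt, patient = pid,
                                              panel = pn,
                                              results = res_counts[[k]],
                                              stringsAsFactors = FALSE)
      } else {
        panel <- panels[[pn]]
        struct <- list(`Test name` = txt(pn))
        for (a in names(panel$analytes)) {
          am <- panel$analytes[[a]]
          struct[[a]] <- list(magnitude = stats::rnorm(1L, am$mean, am$sd),
                              units = am$units)
        }
        emit(archetype_instance(panel$archetype_id,
                                list(receiverOrderIdentifier = txt(rq),
                                     patient = txt(pid),
                                     testDateTime = txt(dt),
                                     Structure = struct)))
        meta_lab[[lab_counter]] <- data.frame(lab = NA_character_, patient = pid,
                                              panel = pn,
                                              results = length(panel$analytes),
                                              stringsAsFactors = FALSE)
      }
    }
  }
  meta <- list(
    patients = data.frame(patient = pat_ids, clinician = pat_clin,
                          stringsAsFactors = FALSE),
    exams = if (length(meta_exam)) do.call(rbind, meta_exam) else
      data.frame(exam = character(), patient = character(), images = integer()),
    labs = if (length(meta_lab)) do.call(rbind, meta_lab) else
      data.frame(lab = character(), patient = character(), panel = character(),
                 results = integer()))
  list(instances = out[seq_len(oi)], meta = meta, params = params)
}

#' Load a dataset into a store backend
#' @param store ARM or Node+Path store.
#' @param instances Instance list.
#' @return Character vector of keys (invisible).
#' @export
load_instances <- function(store, instances) {
  fun <- if (inherits(store, "np_store")) np_store_instance else store_instance
  keys <- vapply(instances, function(i) fun(store, i), "")
  invisible(keys)
}

#' Generate a random instance conforming to an archetype
#'
#' Used by round-trip property tests: mandatory nodes are always populated,
#' optional nodes with probability `p_optional`, multiple-occurrence nodes
#' receive 0 to `max_reps` repetitions. Text fields draw unique values from
#' `counter` so identification uniqueness holds across calls.
#'
#' @param archetype Archetype.
#' @param suite Archetype suite (slot targets).
#' @param counter An environment with a numeric `n` (shared across calls).
#' @param p_optional Probability an optional node is populated.
#' @param max_reps Maximum repetitions of a multiple-occurrence node.
#' @return An `arm_instance`.
#' @export
random_instance <- function(archetype, suite = list(),
                            counter = new.env(parent = emptyenv()),
                            p_optional = 0.8, max_reps = 3L) {
  if (is.null(counter$n)) counter$n <- 0L
  next_text <- function() {
    counter$n <- counter$n + 1L
    sprintf("v%08d", counter$n)
  }
  leaf <- function(type) {
    fields <- resolve_field_columns(type)
    rec <- list()
    for (i in seq_len(nrow(fields))) {
      rec[[fields$suffix[i]]] <- switch(fields$kind[i],
                                        NVARCHAR = next_text(),
                                        INTEGER = sample.int(1000L, 1L),
                                        FLOAT = stats::runif(1L, 0, 1000))
    }
    rec
  }
  gen_nodes <- function(nodes, p) {
    out <- list()
    for (n in nodes) {
      mandatory <- n$occurrence$lower >= 1L
      many <- occ_many(n$occurrence)
      make_one <- function(pp) switch(n$kind,
                                      basic = leaf(n$type),
                                      collection = gen_nodes(n$children, pp),
                                      slot = gen_nodes(suite[[n$target]]$nodes, pp))
      if (many) {
        k <- sample.int(max_reps + 1L, 1L) - 1L
        if (mandatory) k <- max(k, 1L)
        reps <- lapply(seq_len(k), function(i) make_one(p))
        out[[n$name]] <- reps[vapply(reps, length, 0L) > 0L]
      } else if (mandatory || stats::runif(1L) < p) {
        v <- make_one(p)
        if (!length(v) && mandatory) v <- make_one(1)  # force-populate subtree
        if (length(v)) out[[n$name]] <- v
      }
    }
    out
  }
  archetype_instance(archetype$id, gen_nodes(archetype$nodes, p_optional))
}
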