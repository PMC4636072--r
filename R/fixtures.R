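# The worked fixture suite: 17 archetypes covering an integrated-viewer
# workload (patient demographics, imaging exam requests/exams/images, lab
# test requests/results), 5 templates carrying the ARM constraints, and 5
# EAV mappings binding the specialized lab-result archetypes to the
# generalized one. Shipped as dialect files under inst/extdata and parsed by
# build_fixture_suite(); the in-code definitions below are the source the
# files are generated from.

#' Analyte panels of the specialized laboratory archetypes
#'
#' Units and sampling distributions (normal around clinical reference
#' midpoints, with tails crossing the benchmark query thresholds so
#' threshold searches select proper nonempty subsets).
#'
#' @return Named list of panels: each has `archetype_id` and `analytes`
#'   (name -> list(units, mean, sd)).
#' @export
analyte_panels <- function() {
  list(
    blood_gases = list(
      archetype_id = "openEHR-EHR-OBSERVATION.lab_test-blood_gases.v1",
      analytes = list(
        "PaO2" = list(units = "mmHg", mean = 150, sd = 60),
        "PaCO2" = list(units = "mmHg", mean = 40, sd = 8),
        "Arterial pH" = list(units = "pH", mean = 7.38, sd = 0.08),
        "SaO2" = list(units = "%", mean = 97, sd = 2),
        "CaO2" = list(units = "%", mean = 18, sd = 3))),
    full_blood_count = list(
      archetype_id = "openEHR-EHR-OBSERVATION.lab_test-full_blood_count.v1",
      analytes = list(
        "Red cell count" = list(units = "10*12/L", mean = 4.0, sd = 1.1),
        "White cell count" = list(units = "10*9/L", mean = 7.5, sd = 2.5),
        "Haemoglobin" = list(units = "g/dL", mean = 14, sd = 2))),
    liver_function = list(
      archetype_id = "openEHR-EHR-OBSERVATION.lab_test-liver_function.v1",
      analytes = list(
        "Alkaline phosphatase" = list(units = "IU/L", mean = 80, sd = 30),
        "Alanine aminotransferase" = list(units = "IU/L", mean = 30, sd = 15))),
    thyroid = list(
      archetype_id = "openEHR-EHR-OBSERVATION.lab_test-thyroid.v1",
      analytes = list(
        "Thyroid stimulating hormone" = list(units = "uIU/mL", mean = 2.0, sd = 1.2),
        "Free thyroxine" = list(units = "ng/dL", mean = 1.2, sd = 0.3))),
    urea_and_electrolytes = list(
      archetype_id = "openEHR-EHR-OBSERVATION.lab_test-urea_and_electrolytes.v1",
      analytes = list(
        "Sodium" = list(units = "mmol/L", mean = 140, sd = 3),
        "Potassium" = list(units = "mmol/L", mean = 4.2, sd = 0.5))))
}

lab_test_base_nodes <- function() {
  list(basic_item("receiverOrderIdentifier", "DvText", "0..1"),
       basic_item("patient", "DvText", "1..1"),
       basic_item("testDateTime", "DvDateTime", "0..1"),
       collection_item("Structure", "ITEM_TREE",
                       list(basic_item("Test name", "DvText", "0..1")), "1..1"),
       slot_item("annotation", "openEHR-EHR-CLUSTER.lab_result_annotation.v1",
                 "0..1"))
}

# base nodes with extra items appended inside [Structure]
lab_test_specialized_nodes <- function(extra) {
  nodes <- lab_test_base_nodes()
  nodes[[4L]]$children <- c(nodes[[4L]]$children, extra)
  nodes
}

request_nodes <- function(idi_first = TRUE) {
  core <- list(basic_item("requestorIdentifier", "DvText", "0..1"),
               basic_item("receiverIdentifier", "DvText",
                          if (idi_first) "0..1" else "1..1"),
               basic_item("patient", "DvText", "1..1"),
               basic_item("requestDateTime", "DvDateTime", "0..1"),
               slot_item("requestor", "openEHR-EHR-CLUSTER.person_name.v1", "0..1"),
               slot_item("receiver", "openEHR-EHR-CLUSTER.organisation.v1", "0..1"))
  if (idi_first) c(list(basic_item("id", "DvIdentifier", "1..1")), core) else core
}

#' In-code definitions of the fixture archetypes
#' @return Named list of 17 archetypes.
#' @export
fixture_archetype_definitions <- function() {
  lab_test_id <- "openEHR-EHR-OBSERVATION.lab_test.v1"
  panels <- analyte_panels()
  quantity_items <- function(panel)
    lapply(names(panel$analytes), function(a) basic_item(a, "DvQuantity", "0..1"))

  defs <- list(
    archetype("openEHR-DEMOGRAPHIC-CLUSTER.person_identifier.v1", list(
      basic_item("identifier", "DvIdentifier", "1..1"),
      basic_item("type", "DvText", "0..1"))),
    archetype("openEHR-DEMOGRAPHIC-PARTY_IDENTITY.person_name.v1", list(
      basic_item("name", "DvText", "0..1"))),
    archetype("openEHR-DEMOGRAPHIC-ITEM_TREE.person_details.v1", list(
      basic_item("sex", "DvCodedText", "0..1"),
      basic_item("address", "DvText", "0..1"))),
    archetype("openEHR-DEMOGRAPHIC-PERSON.person-patient.v1", list(
      slot_item("patientIdentifier",
                "openEHR-DEMOGRAPHIC-CLUSTER.person_identifier.v1", "1..1"),
      slot_item("patientName",
                "openEHR-DEMOGRAPHIC-PARTY_IDENTITY.person_name.v1", "0..1"),
      slot_item("details",
                "openEHR-DEMOGRAPHIC-ITEM_TREE.person_details.v1", "0..1"),
      basic_item("clinician", "DvText", "0..1"))),
    archetype("openEHR-EHR-CLUSTER.person_name.v1", list(
      basic_item("name", "DvText", "0..1"))),
    archetype("openEHR-EHR-CLUSTER.organisation.v1", list(
      basic_item("name", "DvText", "0..1"),
      basic_item("identifier", "DvIdentifier", "0..1"))),
    archetype("openEHR-EHR-CLUSTER.lab_result_annotation.v1", list(
      basic_item("comment", "DvText", "0..1"))),
    archetype("openEHR-EHR-INSTRUCTION.request-imaging_exam.v1",
              request_nodes(idi_first = TRUE)),
    archetype("openEHR-EHR-OBSERVATION.imaging_exam.v1", list(
      basic_item("id", "DvIdentifier", "1..1"),
      basic_item("receiverOrderIdentifier", "DvIdentifier", "0..1"),
      basic_item("patient", "DvText", "1..1"),
      basic_item("examDateTime", "DvDateTime", "0..1"),
      collection_item("Image details", "CLUSTER", list(
        basic_item("image", "DvMultimedia", "0..1"),
        basic_item("imageType", "DvText", "0..1")), "0..*"))),
    archetype("openEHR-EHR-INSTRUCTION.request-lab_test.v1",
              request_nodes(idi_first = FALSE)),
    archetype(lab_test_id, lab_test_base_nodes()),
    archetype("openEHR-EHR-OBSERVATION.lab_test-general.v1",
              c(list(basic_item("id", "DvIdentifier", "1..1")),
                lab_test_specialized_nodes(list(
                  collection_item("Result", "CLUSTER", list(
                    basic_item("Test item", "DvText", "0..1"),
                    basic_item("Result", "DvText", "0..1"),
                    basic_item("Result unit", "DvText", "0..1")), "0..*")))),
              parent = lab_test_id)
  )
  for (panel in analyte_panels()) {
    defs[[length(defs) + 1L]] <-
      archetype(panel$archetype_id,
                lab_test_specialized_nodes(quantity_items(panel)),
                parent = lab_test_id)
  }
  stats::setNames(defs, vapply(defs, `[[`, "", "id"))
}

#' In-code definitions of the fixture templates
#' @return List of 5 templates (one per entry-level archetype).
#' @export
fixture_template_definitions <- function() {
  list(
    template("PERSON.person-patient.v1.oet",
             "openEHR-DEMOGRAPHIC-PERSON.person-patient.v1",
             arm_constraints(
               identification_item = "[patientIdentifier]/[identifier]")),
    template("INSTRUCTION.request-imaging_exam.v1.oet",
             "openEHR-EHR-INSTRUCTION.request-imaging_exam.v1",
             arm_constraints(
               identification_item = "[id]",
               query_items = c("[requestorIdentifier]", "[patient]",
                               "[receiverIdentifier]"))),
    template("INSTRUCTION.request-lab_test.v1.oet",
             "openEHR-EHR-INSTRUCTION.request-lab_test.v1",
             arm_constraints(
               identification_item = "[receiverIdentifier]",
               query_items = c("[requestorIdentifier]", "[patient]"))),
    template("OBSERVATION.imaging_exam.v1.oet",
             "openEHR-EHR-OBSERVATION.imaging_exam.v1",
             arm_constraints(
               identification_item = "[id]",
               query_items = c("[receiverOrderIdentifier]", "[patient]"))),
    template("OBSERVATION.lab_test-general.v1.oet",
             "openEHR-EHR-OBSERVATION.lab_test-general.v1",
             arm_constraints(
               identification_item = "[id]",
               query_items = c("[receiverOrderIdentifier]", "[patient]"))))
}

#' In-code definitions of the fixture EAV mappings
#' @return Named list of 5 mappings keyed by specialized archetype id.
#' @export
fixture_eav_definitions <- function() {
  gen <- "openEHR-EHR-OBSERVATION.lab_test-general.v1"
  maps <- lapply(analyte_panels(), function(panel) {
    nm <- do.call(rbind, lapply(names(panel$analytes), function(a)
      data.frame(source = paste0("[", a, "]"), set = "en",
                 target = "[Test item]/value/value", stringsAsFactors = FALSE)))
    fl <- do.call(rbind, lapply(names(panel$analytes), function(a)
      data.frame(source = c(paste0("[", a, "]/value/magnitude"),
                            paste0("[", a, "]/value/units")),
                 target = c("[Result]/value/value", "[Result unit]/value/value"),
                 stringsAsFactors = FALSE)))
    eav_mapping(panel$archetype_id, gen, name_entries = nm, field_entries = fl)
  })
  stats::setNames(maps, vapply(maps, `[[`, "", "specialized_archetype_id"))
}

#' Write the fixture suite as dialect files
#' @param dir Target directory (subdirs `archetypes/`, `templates/`, `eav/`).
#' @export
write_fixture_files <- function(dir) {
  for (d in file.path(dir, c("archetypes", "templates", "eav")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (a in fixture_archetype_definitions())
    writeLines(serialize_archetype(a),
               file.path(dir, "archetypes", paste0(a$id, ".yaml")))
  for (t in fixture_template_definitions())
    writeLines(serialize_template(t),
               file.path(dir, "templates", paste0(t$template_id, ".yaml")))
  for (m in fixture_eav_definitions())
    writeLines(serialize_eav_mapping(m),
               file.path(dir, "eav", paste0(m$specialized_archetype_id, ".xml")))
  invisible(dir)
}

#' Load the fixture suite
#'
#' Parses the shipped archetype/template/EAV dialect files: 17 archetypes
#' (16 reused plus the newly designed generalized lab-result archetype),
#' the 5 templates with their ARM constraints, and the 5 EAV mappings of the
#' specialized lab-result archetypes.
#'
#' @param dir Directory holding the fixture files (default: the installed
#'   package's `extdata`).
#' @return List with `archetypes` (named by id), `templates` (named by
#'   archetype id), `eav_maps` (named by specialized archetype id).
#' @export
build_fixture_suite <- function(dir = system.file("extdata",
                                                  package = "armpersist")) {
  afiles <- sort(list.files(file.path(dir, "archetypes"), full.names = TRUE))
  archetypes <- lapply(afiles, read_archetype)
  names(archetypes) <- vapply(archetypes, `[[`, "", "id")
  # closure: parents and slot targets must live in the suite
  for (a in archetypes) {
    if (!is.null(a$parent) && is.null(archetypes[[a$parent]]))
      abort2("dangling_parent", "parent %s of %s missing from suite",
             a$parent, a$id)
    for (n in arch_nodes_flat(a))
      if (identical(n$kind, "slot") && is.null(archetypes[[n$target]]))
        abort2("unresolved_slot", "slot target %s of %s missing from suite",
               n$target, a$id)
  }
  tfiles <- sort(list.files(file.path(dir, "templates"), full.names = TRUE))
  templates <- lapply(tfiles, read_template)
  names(templates) <- vapply(templates, `[[`, "", "archetype_id")
  efiles <- sort(list.files(file.path(dir, "eav"), full.names = TRUE))
  eav_maps <- lapply(efiles, read_eav_mapping)
  names(eav_maps) <- vapply(eav_maps, `[[`, "", "specialized_archetype_id")
  list(archetypes = archetypes, templates = templates, eav_maps = eav_maps)
}

#' Map the fixture suite to its schema
#' @param suite Fixture suite from [build_fixture_suite()].
#' @param config Schema configuration.
#' @return Schema model.
#' @export
map_fixture_schema <- function(suite = build_fixture_suite(),
                               config = schema_config()) {
  map_schema(suite$archetypes, suite$templates, suite$eav_maps, config)
}

#' Load the golden schema model
#' @param path JSON file (default: shipped golden model).
#' @return Parsed golden schema (list form).
#' @export
golden_schema <- function(path = system.file("extdata", "golden_schema.json",
                                             package = "armpersist")) {
  jsonlite::fromJSON(paste(readLines(path, encoding = "UTF-8"), collapse = "\n"),
                     simplifyVector = FALSE)
}
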