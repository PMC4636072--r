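# Templates adapt an archetype to the local EHR context and carry the ARM
# persistence constraints: at most one identification data item (IDI) that
# becomes the unique clustered key, query data items (QDIs) that become
# non-clustered indexes and may propagate into child tables, and optional
# suppression of individual propagations.

#' Construct ARM constraints
#' @param identification_item Optional node path of the IDI.
#' @param query_items Character vector of QDI node paths.
#' @param suppressed_propagations List of `list(group, query_item)` pairs:
#'   the named query item is not propagated into the child table mapped from
#'   the named multi-occurrence group or slot.
#' @return An `arm_constraints` object.
#' @export
arm_constraints <- function(identification_item = NULL, query_items = character(),
                            suppressed_propagations = list()) {
  if (!is.null(identification_item) && length(identification_item) > 1L)
    abort2("duplicate_idi", "only one identification data item may exist per archetype")
  structure(list(identification_item = identification_item,
                 query_items = as.character(query_items),
                 suppressed_propagations = suppressed_propagations),
            class = "arm_constraints")
}

#' Construct a template
#'
#' One template binds to exactly one archetype. Optionality overrides may
#' only tighten occurrences; `slot_fills` restricts slots to named archetype
#' ids; `arm` carries the persistence constraints.
#'
#' @param template_id Template id (conventionally `<archetype>.oet`).
#' @param archetype_id Id of the archetype the template constrains.
#' @param arm [arm_constraints()] object.
#' @param optionality_overrides Named list: node path -> occurrence string.
#' @param default_values Named list: node path -> literal.
#' @param slot_fills Named list: slot path -> archetype id.
#' @return An `arm_template` object.
#' @export
template <- function(template_id, archetype_id, arm = arm_constraints(),
                     optionality_overrides = list(), default_values = list(),
                     slot_fills = list()) {
  structure(list(template_id = template_id, archetype_id = archetype_id,
                 optionality_overrides = optionality_overrides,
                 default_values = default_values, slot_fills = slot_fills,
                 arm = arm),
            class = "arm_template")
}

#' Parse a template from its YAML/JSON dialect
#'
#' A document listing more than one identification item is rejected at parse
#' time; references to archetype content are checked later by
#' [validate_template()], not here.
#'
#' @param definition_text Document text.
#' @return An `arm_template`.
#' @export
parse_template <- function(definition_text) {
  doc <- tryCatch(yaml::yaml.load(definition_text),
                  error = function(e)
                    abort2("syntax_error", "template syntax error: %s",
                           conditionMessage(e)))
  if (!is.list(doc) || is.null(doc$template_id) || is.null(doc$archetype_id))
    abort2("syntax_error", "template document lacks template_id/archetype_id")
  armdoc <- doc$arm %||% list()
  idi <- armdoc$identification_item
  if (length(idi) > 1L)
    abort2("duplicate_idi", "template %s lists %d identification data items",
           doc$template_id, length(idi))
  template(doc$template_id, doc$archetype_id,
           arm = arm_constraints(
             identification_item = if (length(idi)) idi[[1L]] else NULL,
             query_items = unlist(armdoc$query_items) %||% character(),
             suppressed_propagations = armdoc$suppressed_propagations %||% list()),
           optionality_overrides = doc$optionality %||% list(),
           default_values = doc$defaults %||% list(),
           slot_fills = doc$slot_fills %||% list())
}

#' Serialize a template to YAML
#' @param tpl Template.
#' @export
serialize_template <- function(tpl) {
  yaml::as.yaml(list(
    template_id = tpl$template_id,
    archetype_id = tpl$archetype_id,
    arm = list(identification_item = tpl$arm$identification_item,
               query_items = as.list(tpl$arm$query_items),
               suppressed_propagations = tpl$arm$suppressed_propagations),
    optionality = tpl$optionality_overrides,
    defaults = tpl$default_values,
    slot_fills = tpl$slot_fills))
}

#' Read a template dialect file
#' @param path File path.
#' @export
read_template <- function(path)
  parse_template(paste(readLines(path, encoding = "UTF-8"), collapse = "\n"))

violation <- function(code, path, message)
  data.frame(code = code, path = path %||% NA_character_, message = message,
             stringsAsFactors = FALSE)

no_violations <- function()
  data.frame(code = character(), path = character(), message = character(),
             stringsAsFactors = FALSE)

# Effective occurrence of a node reached through `through` ancestors: the
# upper bound is MANY when any traversed slot/collection repeats.
effective_single <- function(resolved)
  all(!vapply(resolved$through, function(n) occ_many(n$occurrence), TRUE))

#' Validate a template against its archetype
#'
#' Violations are returned as data, not raised: the report is empty iff all
#' ARM constraints hold. Checks that the IDI and every QDI resolve to basic
#' items (collections and slots cannot carry these roles), that the IDI's
#' occurrence is `0..1` or `1..1` along its whole path, that optionality
#' overrides only tighten, and that slot fills target the named slots.
#'
#' @param tpl Template.
#' @param archetype The archetype named by `tpl$archetype_id`.
#' @param suite Optional named list of archetypes so constraint paths may
#'   resolve through single-occurrence slots.
#' @return A data.frame of violations (`code`, `path`, `message`).
#' @export
validate_template <- function(tpl, archetype, suite = NULL) {
  stopifnot(inherits(tpl, "arm_template"), inherits(archetype, "arm_archetype"))
  if (!identical(tpl$archetype_id, archetype$id))
    abort2("template_mismatch", "template %s does not bind archetype %s",
           tpl$template_id, archetype$id)
  out <- no_violations()
  check_item <- function(path, role) {
    r <- find_node(archetype, path, suite)
    if (is.null(r))
      return(violation("unresolved_path", path,
                       sprintf("%s path does not resolve", role)))
    if (!identical(r$node$kind, "basic"))
      return(violation("collection_as_constraint", path,
                       sprintf("%s item is a %s; only basic data items may carry this role",
                               role, r$node$kind)))
    if (role == "identification") {
      occ <- r$node$occurrence
      if (occ_many(occ) || !effective_single(r))
        return(violation("idi_occurrence", path,
                         "identification data item must have occurrence 0..1 or 1..1"))
    }
    no_violations()
  }
  if (!is.null(tpl$arm$identification_item))
    out <- rbind(out, check_item(tpl$arm$identification_item, "identification"))
  for (q in tpl$arm$query_items)
    out <- rbind(out, check_item(q, "query"))
  for (p in names(tpl$optionality_overrides)) {
    r <- find_node(archetype, p, suite)
    if (is.null(r)) { out <- rbind(out, violation("unresolved_path", p,
                                                  "override path does not resolve")); next }
    ov <- occurrence(tpl$optionality_overrides[[p]])
    oc <- r$node$occurrence
    tightens <- ov$lower >= oc$lower && (occ_many(oc) || !occ_many(ov))
    if (!tightens)
      out <- rbind(out, violation("loosening_override", p,
                                  "optionality override may only tighten the occurrence"))
  }
  for (p in names(tpl$slot_fills)) {
    r <- find_node(archetype, p, suite)
    if (is.null(r) || !identical(r$node$kind, "slot"))
      out <- rbind(out, violation("bad_slot_fill", p, "slot fill does not name a slot"))
  }
  out
}
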