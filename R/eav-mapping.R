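# Mappings between a specialized archetype and the generalized archetype that
# stores the same logical content as name/value/unit triples. The XML dialect
# carries one <eav> element naming the generalized target, one
# <eavAttributeName> per mapped item (its display name, in the language named
# by `set`, is written into the target name item), and one
# <eavAttributeField> per mapped field.

#' Construct an EAV mapping
#' @param specialized_archetype_id,generalized_archetype_id Archetype ids.
#' @param name_entries data.frame(source, set, target): source item path,
#'   ontology language set, target name-item field path.
#' @param field_entries data.frame(source, target): source field path ->
#'   target field path.
#' @return An `arm_eav_mapping`.
#' @export
eav_mapping <- function(specialized_archetype_id, generalized_archetype_id,
                        name_entries = NULL, field_entries = NULL) {
  empty_n <- data.frame(source = character(), set = character(),
                        target = character(), stringsAsFactors = FALSE)
  empty_f <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  structure(list(specialized_archetype_id = specialized_archetype_id,
                 generalized_archetype_id = generalized_archetype_id,
                 name_entries = name_entries %||% empty_n,
                 field_entries = field_entries %||% empty_f),
            class = "arm_eav_mapping")
}

# Normalize a path in the Table-style dialect: trim outer whitespace and
# whitespace just inside brackets; leave case untouched.
normalize_eav_path <- function(p) {
  p <- trimws(p)
  gsub("\\[\\s*([^]]*?)\\s*\\]", "[\\1]", p, perl = TRUE)
}

# "[White cell count]/value/magnitude" -> item path "[White cell count]"
eav_item_path <- function(p) sub("/value/.*$", "", normalize_eav_path(p))
# trailing field suffix after "/value/" (NA when absent)
eav_field_suffix <- function(p) {
  m <- regmatches(p, regexec(".*/value/(.+)$", p))[[1L]]
  if (length(m) == 2L) m[[2L]] else NA_character_
}

#' Parse an EAV mapping document
#'
#' Accepts either a rooted document (any root element whose children are the
#' mapping elements) or a bare sequence of `<eav>`, `<eavAttributeName>`,
#' `<eavAttributeField>` elements. Any other element name is an error.
#'
#' @param xml_text XML text.
#' @param specialized_archetype_id Id of the specialized archetype the
#'   document belongs to; may instead be given as an `archetype` attribute on
#'   the document root.
#' @return An `arm_eav_mapping`.
#' @export
parse_eav_mapping <- function(xml_text, specialized_archetype_id = NULL) {
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) NULL)
  if (is.null(doc)) {
    # Table-style fragment: sibling top-level elements; wrap and retry
    doc <- tryCatch(xml2::read_xml(paste0("<eavMapping>", xml_text, "</eavMapping>")),
                    error = function(e)
                      abort2("syntax_error", "EAV mapping XML is not well-formed: %s",
                             conditionMessage(e)))
  }
  root <- xml2::xml_root(doc)
  kids <- xml2::xml_children(root)
  if (xml2::xml_name(root) %in% c("eav", "eavAttributeName", "eavAttributeField")) {
    kids <- list(root)
  }
  spec_id <- specialized_archetype_id %||% xml2::xml_attr(root, "archetype")
  gen_id <- NULL
  nm <- list(); fl <- list()
  for (el in kids) {
    tag <- xml2::xml_name(el)
    if (tag == "eav") {
      gen_id <- xml2::xml_attr(el, "name")
      if (is.na(gen_id)) abort2("missing_attribute", "<eav> lacks a name attribute")
    } else if (tag == "eavAttributeName") {
      src <- xml2::xml_attr(el, "name")
      if (is.na(src)) abort2("missing_attribute", "<eavAttributeName> lacks a name attribute")
      nm[[length(nm) + 1L]] <- data.frame(
        source = normalize_eav_path(src),
        set = xml2::xml_attr(el, "set"),
        target = normalize_eav_path(xml2::xml_text(el)),
        stringsAsFactors = FALSE)
    } else if (tag == "eavAttributeField") {
      src <- xml2::xml_attr(el, "name")
      if (is.na(src)) abort2("missing_attribute", "<eavAttributeField> lacks a name attribute")
      fl[[length(fl) + 1L]] <- data.frame(
        source = normalize_eav_path(src),
        target = normalize_eav_path(xml2::xml_text(el)),
        stringsAsFactors = FALSE)
    } else {
      abort2("unknown_element", "unknown EAV mapping element <%s>", tag)
    }
  }
  if (is.null(gen_id))
    abort2("syntax_error", "EAV mapping lacks an <eav> element naming the generalized archetype")
  eav_mapping(spec_id, gen_id,
              name_entries = if (length(nm)) do.call(rbind, nm) else NULL,
              field_entries = if (length(fl)) do.call(rbind, fl) else NULL)
}

#' Serialize an EAV mapping to XML
#' @param m EAV mapping.
#' @return XML text (rooted, deterministic element order).
#' @export
serialize_eav_mapping <- function(m) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(sprintf('<eavMapping archetype="%s">', esc(m$specialized_archetype_id)),
             sprintf('  <eav name="%s"></eav>', esc(m$generalized_archetype_id)))
  for (i in seq_len(nrow(m$name_entries)))
    lines <- c(lines, sprintf('  <eavAttributeName name="%s" set="%s">%s</eavAttributeName>',
                              esc(m$name_entries$source[i]), esc(m$name_entries$set[i]),
                              esc(m$name_entries$target[i])))
  for (i in seq_len(nrow(m$field_entries)))
    lines <- c(lines, sprintf('  <eavAttributeField name="%s">%s</eavAttributeField>',
                              esc(m$field_entries$source[i]), esc(m$field_entries$target[i])))
  paste(c(lines, "</eavMapping>"), collapse = "\n")
}

#' Read an EAV mapping file
#' @param path File path.
#' @param specialized_archetype_id Optional override of the root attribute.
#' @export
read_eav_mapping <- function(path, specialized_archetype_id = NULL)
  parse_eav_mapping(paste(readLines(path, encoding = "UTF-8"), collapse = "\n"),
                    specialized_archetype_id = specialized_archetype_id)

# Locate the unique multi-occurrence group of the generalized archetype that
# hosts a (short) target path like "[Test item]/value/value": the group whose
# children include an item of that name.
resolve_generalized_target <- function(generalized, target_path) {
  item <- basename_path(eav_item_path(target_path))
  hits <- list()
  for (n in arch_nodes_flat(generalized)) {
    if (identical(n$kind, "collection") && occ_many(n$occurrence)) {
      kid_names <- vapply(n$children, `[[`, "", "name")
      if (item %in% kid_names)
        hits[[length(hits) + 1L]] <-
          list(group = n, item = n$children[[match(item, kid_names)]])
    }
  }
  if (length(hits) != 1L) return(NULL)
  hits[[1L]]
}

#' Validate an EAV mapping against its archetypes
#'
#' Checks that every source path names an item of the specialized archetype,
#' that every target path resolves into exactly one multiple-occurrence group
#' of the generalized archetype, and that each source field of a mapped item
#' maps to a distinct target field.
#'
#' @param m EAV mapping.
#' @param specialized,generalized The two archetypes.
#' @return Violation data.frame as for [validate_template()].
#' @export
validate_eav_mapping <- function(m, specialized, generalized) {
  out <- no_violations()
  group_ids <- character()
  for (tp in c(m$name_entries$target, m$field_entries$target)) {
    r <- resolve_generalized_target(generalized, tp)
    if (is.null(r)) {
      out <- rbind(out, violation("unresolved_target", tp,
                                  "target path absent from generalized archetype"))
    } else group_ids <- c(group_ids, r$group$path)
  }
  if (length(unique(group_ids)) > 1L)
    out <- rbind(out, violation("split_group", NA_character_,
                                "target paths span more than one multiple-occurrence group"))
  src_items <- unique(c(eav_item_path(m$name_entries$source),
                        vapply(m$field_entries$source, eav_item_path, "")))
  for (sp in src_items) {
    hit <- find_item_by_name(specialized, basename_path(sp))
    if (is.null(hit))
      out <- rbind(out, violation("unresolved_source", sp,
                                  "source item absent from specialized archetype"))
  }
  for (sp in src_items) {
    rows <- m$field_entries[vapply(m$field_entries$source, eav_item_path, "") == sp, ,
                            drop = FALSE]
    if (anyDuplicated(rows$target))
      out <- rbind(out, violation("duplicate_target_field", sp,
                                  "source fields of one item must map to distinct target fields"))
  }
  out
}

# Find a basic item anywhere in the archetype by its (unique) name.
find_item_by_name <- function(a, name) {
  for (n in arch_nodes_flat(a))
    if (identical(n$kind, "basic") && identical(n$name, name)) return(n)
  NULL
}
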